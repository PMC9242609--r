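"incentive_id","observed_inr"
"anc_series",789
"pnc_series",376
"full_immunization_y1",397
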