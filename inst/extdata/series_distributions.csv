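"incentive_id","count","probability"
"anc_series",0,0.25
"anc_series",1,0.2
"anc_series",2,0.15
"anc_series",3,0.136
"anc_series",4,0.264
"pnc_series",0,0.1
"pnc_series",1,0.15
"pnc_series",2,0.15
"pnc_series",3,0.15
"pnc_series",4,0.12
"pnc_series",5,0.11
"pnc_series",6,0.12
"pnc_series",7,0.1
"full_immunization_y1",0,0.08
"full_immunization_y1",1,0.1
"full_immunization_y1",2,0.12
"full_immunization_y1",3,0.1
"full_immunization_y1",4,0.089
"full_immunization_y1",5,0.511
"full_immunization_y2",0,0.3
"full_immunization_y2",1,0.3
"full_immunization_y2",2,0.4
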