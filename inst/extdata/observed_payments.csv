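"category","mean_monthly_inr","fiscal_year","source"
"ROUTINE",941,"2017-2018","state payment records (bundled fixture)"
"ANC_ID",789,"2017-2018","state payment records (bundled fixture)"
"PNC",376,"2017-2018","state payment records (bundled fixture)"
"IMMUNIZATION",387,"2017-2018","state payment records (bundled fixture)"
"FP",87,"2017-2018","state payment records (bundled fixture)"
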