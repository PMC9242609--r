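"quantity","inr_per_month"
"pp",5867
"pa",3000
"aa",1325
"observed",2580
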