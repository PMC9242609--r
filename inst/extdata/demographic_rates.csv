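"key","value","basis","description","source"
"PREGNANCY",27.28,"PER_1000_PER_YEAR","annual crude birth rate, rural; proxies monthly pregnant-woman incidence","vital-registration bulletin (fixture)"
"NEWBORN",27.28,"PER_1000_PER_YEAR","annual live births per 1,000 population","vital-registration bulletin (fixture)"
"CHILD_U5",0.136,"PROPORTION","children under 5 as a share of total population (census projection)","census projection (fixture)"
"ELIGIBLE_COUPLE",0.17,"PROPORTION","eligible couples as a share of total population","government order (fixture)"
"INFANT_MORTALITY",43,"PER_1000_PER_YEAR","infant deaths per 1,000 live births per year (informational fixture)","vital-registration bulletin (fixture)"
"NEONATAL_MORTALITY",30,"PER_1000_PER_YEAR","neonatal deaths per 1,000 live births per year (informational fixture)","vital-registration report (fixture)"
"SEVERE_WASTING_U5",0.04,"PROPORTION","severely wasted share among children under 5","child nutrition survey (fixture)"
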