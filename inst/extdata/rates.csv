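"key","value","provenance"
"anc_home_visit",0.55,"SYNTHETIC"
"counsel_facility_delivery",0.6,"linked household survey"
"register_pregnancy",0.7,"SYNTHETIC"
"escort_to_facility",0.5,"SYNTHETIC"
"pnc_visit_series",0.22,"SYNTHETIC"
"identify_sick_newborn",0.4,"SYNTHETIC"
"sncu_followup_visit",0.35,"SYNTHETIC"
"visit_underweight_child",0.3,"SYNTHETIC"
"refer_nrc",0.25,"SYNTHETIC"
"counsel_limiting",0.45,"SYNTHETIC"
"counsel_spacing",0.4,"SYNTHETIC"
"home_delivery_contraceptives",0.5,"SYNTHETIC"
"counsel_ppiucd",0.35,"SYNTHETIC"
"mobilize_immunization",0.65,"SYNTHETIC"
"attend_vhnd",0.8,"SYNTHETIC"
"recordkeeping",0.75,"recordkeeping audit"
"update_household_survey",0.7,"SYNTHETIC"
"attend_block_meeting",0.85,"SYNTHETIC"
"update_couple_list",0.6,"SYNTHETIC"
"anc_full_series_given_visit",0.264,"government health statistics"
"facility_delivery_given_counseling",0.66,"linked household survey"
"facility_delivery_given_escort",0.68,"SYNTHETIC"
"sncu_admission_given_referral",0.5,"SYNTHETIC"
"nrc_admission_given_referral",0.35,"SYNTHETIC"
"sterilization_given_counseling",0.04,"SYNTHETIC"
"male_sterilization_given_counseling",0.005,"SYNTHETIC"
"ppiucd_adoption_given_counseling",0.1,"SYNTHETIC"
"spacing_adopted_given_counseling",0.15,"SYNTHETIC"
"full_immunization_given_mobilization",0.511,"national family health survey"
"booster_completion_given_mobilization",0.4,"SYNTHETIC"
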