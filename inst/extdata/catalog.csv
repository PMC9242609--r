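"id","name","category","amount","incidence_basis","action_keys","behavior_keys","series_n_components","series_full_threshold","scaling","basis_multiplier","placeholder_amount"
"anc_series","ANC check-up series (4 check-ups)","ANC_ID",300,"PREGNANCY","anc_home_visit","anc_full_series_given_visit",4,4,"POPULATION",1,FALSE
"inst_delivery","Institutional delivery at public facility","ANC_ID",300,"PREGNANCY","counsel_facility_delivery","facility_delivery_given_counseling",,,"POPULATION",1,FALSE
"preg_registration","Early pregnancy registration","ANC_ID",100,"PREGNANCY","register_pregnancy","",,,"POPULATION",1,TRUE
"delivery_escort","Escort to facility for delivery","ANC_ID",100,"PREGNANCY","escort_to_facility","facility_delivery_given_escort",,,"POPULATION",1,TRUE
"pnc_series","Postnatal home-visit series (6 of 7 visits)","PNC",250,"NEWBORN","pnc_visit_series","",7,6,"POPULATION",1,TRUE
"sick_newborn_referral","Referral of critically sick newborn","PNC",100,"NEWBORN","identify_sick_newborn","sncu_admission_given_referral",,,"POPULATION",0.1,TRUE
"sncu_followup","Follow-up of newborn discharged from SNCU","PNC",50,"NEWBORN","sncu_followup_visit","",,,"POPULATION",0.08,TRUE
"underweight_child_visit","Monthly visit to severely wasted child","PNC",50,"CHILD_U5","visit_underweight_child","",,,"POPULATION",0.04,TRUE
"nrc_referral","Referral to nutritional rehabilitation centre","PNC",100,"CHILD_U5","refer_nrc","nrc_admission_given_referral",,,"POPULATION",0.002,TRUE
"female_sterilization","Female sterilization after 2 children","FP",300,"ELIGIBLE_COUPLE","counsel_limiting","sterilization_given_counseling",,,"POPULATION",0.008,TRUE
"male_sterilization","Male sterilization","FP",400,"ELIGIBLE_COUPLE","counsel_limiting","male_sterilization_given_counseling",,,"POPULATION",5e-04,TRUE
"ppiucd","Postpartum IUCD adoption","FP",150,"PREGNANCY","counsel_ppiucd","ppiucd_adoption_given_counseling",,,"POPULATION",1,TRUE
"birth_spacing","Two-year birth spacing","FP",500,"ELIGIBLE_COUPLE","counsel_spacing","spacing_adopted_given_counseling",,,"POPULATION",0.01,TRUE
"contraceptive_distribution","Home delivery of contraceptives","FP",50,"ELIGIBLE_COUPLE","home_delivery_contraceptives","",,,"POPULATION",0.02,TRUE
"unmet_need_followup","Follow-up of couples with unmet need","FP",100,"ELIGIBLE_COUPLE","counsel_spacing","",,,"POPULATION",0.005,TRUE
"full_immunization_y1","Full immunization in first year","IMMUNIZATION",100,"NEWBORN","mobilize_immunization","full_immunization_given_mobilization",5,5,"POPULATION",1,FALSE
"full_immunization_y2","Completion of boosters in second year","IMMUNIZATION",50,"NEWBORN","mobilize_immunization","booster_completion_given_mobilization",2,2,"POPULATION",1,TRUE
"vhnd_mobilization","Village health and nutrition day mobilization","IMMUNIZATION",150,"ROUTINE","attend_vhnd","",,,"FIXED",1,TRUE
"imm_session_support","Immunization session support","IMMUNIZATION",50,"NEWBORN","mobilize_immunization","",,,"POPULATION",1,TRUE
"recordkeeping","Monthly recordkeeping of births and deaths","ROUTINE",100,"ROUTINE","recordkeeping","",,,"FIXED",1,FALSE
"household_survey_update","Village household survey update","ROUTINE",100,"ROUTINE","update_household_survey","",,,"FIXED",1,TRUE
"monthly_meeting","Attendance at monthly block meeting","ROUTINE",150,"ROUTINE","attend_block_meeting","",,,"FIXED",1,TRUE
"eligible_couple_list","Eligible-couple register update","ROUTINE",100,"ROUTINE","update_couple_list","",,,"FIXED",1,TRUE
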