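patient_id,findings,neuromuscular_onset,vital_status,prenatal_death,age_at_death_months,age_at_last_followup_months,liver_transplant,age_at_transplant_months,explicit_normal_hepatic,explicit_normal_neuromuscular,explicit_normal_cardiac,death_attributed_hepatic
E01,hypotonia;ventilator_dependent_respiratory_weakness,at_birth,deceased,FALSE,1.5,,unknown,,TRUE,FALSE,TRUE,
E02,hepatomegaly;elevated_alt,unknown,alive,FALSE,,96,unknown,,FALSE,TRUE,FALSE,
E03,liver_failure;jaundice;hepatomegaly,unknown,alive,FALSE,,60,yes,18,FALSE,TRUE,TRUE,
E04,hypotonia;hepatomegaly;splenomegaly:platelet_count=110000,at_birth,deceased,FALSE,20,,unknown,,FALSE,FALSE,FALSE,TRUE
E05,cardiomyopathy,unknown,alive,FALSE,,140,unknown,,TRUE,TRUE,FALSE,
E06,hypotonia,unknown,alive,FALSE,,30,unknown,,FALSE,FALSE,FALSE,
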