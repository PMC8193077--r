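outcome_id,name,clean_window_days,require_inpatient,require_primary_position
non_haemorrhagic_stroke,Non-haemorrhagic stroke,365,TRUE,FALSE
haemorrhagic_stroke,Haemorrhagic stroke,365,TRUE,FALSE
acute_myocardial_infarction,Acute myocardial infarction,365,TRUE,FALSE
deep_vein_thrombosis,Deep vein thrombosis,365,FALSE,FALSE
pulmonary_embolism,Pulmonary embolism,365,FALSE,FALSE
anaphylaxis,Anaphylaxis,30,FALSE,FALSE
bell_palsy,Bell's palsy (facial nerve palsy),183,FALSE,FALSE
myocarditis_pericarditis,Myocarditis or pericarditis,365,FALSE,FALSE
narcolepsy,Narcolepsy,365,FALSE,FALSE
appendicitis,Appendicitis,365,FALSE,FALSE
immune_thrombocytopenia,Immune thrombocytopenia,365,FALSE,FALSE
disseminated_intravascular_coagulation,Disseminated intravascular coagulation,365,FALSE,FALSE
encephalomyelitis,Encephalomyelitis (incl. ADEM),183,TRUE,FALSE
guillain_barre_syndrome,Guillain-Barre syndrome,365,TRUE,TRUE
transverse_myelitis,Transverse myelitis,365,FALSE,FALSE
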