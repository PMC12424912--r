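study,subject_id,type,condition,sex,age_group
UK_BB_2025,62412,Relative,R50.9,Female,A40_49
GTEx_v8,67099,Donor,M32.9,Male,A50_59
GTEx_v8,56187,Relative,B34.9,Male,A80_89
AsthmaTrial,23959,Control,E84.9,Male,A50_59
COPDStudy,7051,Relative,E10.9,Female,A70_79
LiverRegistry,53390,Proband,G20,Unknown,A60_69
CNAG_Cohort,46880,Relative,C61,Male,A70_79
BrainBank,60189,Proband,NA,Not_reported,A30_39
AsthmaTrial,13052,Donor,K21.9,Female,A50_59
UK_BB_2025,17014,Control,G30.9,Not_reported,A40_49
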