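cases.case_id,project.project_id,cases.disease_type,demographics.gender,demographics.age_at_index,cohort
1c484c75,TCGA-LIHC,C22.0,female,45,case
f75a753e,TCGA-LIHC,C22.0,male,62,case
1fd8b806,TCGA-LIHC,C22.0,female,33,case
f75a753e,TCGA-LIHC,C22.0,male,62,case
e521a243,TCGA-LIHC,C22.0,male,58,case
0083a327,TCGA-LIHC,C22.0,male,71,case
7d60b2f8,TCGA-LIHC,C22.0,female,29,case
85972539,TCGA-LIHC,C22.0,female,45,control
ca580b69,TCGA-LIHC,C22.0,male,80,control
3aec652e,TCGA-LIHC,C22.0,female,51,'--
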