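project,species,subject_id,tissue,sample_type,assay,condition,timepoint,duration,batch,replicate
ENCODE,Zebrafish,68133,Bone_marrow,Cell_line,ATAC_seq,J44.9,Collection,P1D,19,1
UK_Biobank,Zebrafish,87615,Liver,Normal,RNA_seq,E11.9,Diagnosis,P0N,85,30
UK_Biobank,Macaque,50977,Brain,Normal,Not_available,B20,Collection,P6M,,
TARGET_AML,Macaque,93272,Brain,Tumor,DNA_seq,K76.0,Treatment,P1M,57,28
CNAG_Test,Macaque,31406,Liver,Normal,Methylome,C22.2,Treatment,P1M,,
ICGC_PACA,Human,71739,Heart,Primary,Methylome,C22.2,Diagnosis,P0N,51,
GTEx,Macaque,65040,Lung,Tumor,WGS,NA,Follow_up,P1W,,6
TARGET_AML,Macaque,26437,Skin,Tumor,RNA_seq,C22.2,Baseline,P6M,23,90
ENCODE,Macaque,49091,Lung,Tumor,ATAC_seq,NA,Follow_up,P1D,,75
CNAG_Test,Macaque,29746,Bone_marrow,Primary,ATAC_seq,I50.9,Follow_up,P1Y,78,
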