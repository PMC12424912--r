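# Example ClarID codebook.
#
# Two entities ("biosample", "subject"); each component maps controlled
# terms to a verbose `code` (human format), a compact `stub_code` (stub
# format), a display `label`, and an ontology CURIE `id` kept for
# reference only. `tax_code` (species) is a reference-only taxonomic
# abbreviation. Clinical conditions are NOT listed here: they come from
# the bundled ICD-10 lookup table. Numeric components (subject_id,
# duration, batch, replicate, condition) are rule-based, under `rules`.
biosample:
  project:
    CNAG_Test:
      code: CNAG_Test
      stub_code: "CT"
      label: "CNAG test project"
      id: "NCIT:C19156"
    TARGET_AML:
      code: TARGET_AML
      stub_code: "TAML"
      label: "TARGET Acute Myeloid Leukemia"
      id: "NCIT:C17998"
    GTEx:
      code: GTEx
      stub_code: "G"
      label: "Genotype-Tissue Expression"
      id: "NCIT:C125602"
    UK_Biobank:
      code: UK_Biobank
      stub_code: "UKB"
      label: "UK Biobank"
      id: "NCIT:C101411"
    ENCODE:
      code: ENCODE
      stub_code: "EN"
      label: "Encyclopedia of DNA Elements"
      id: "NCIT:C172216"
    ICGC_PACA:
      code: ICGC_PACA
      stub_code: "IPAC"
      label: "ICGC Pancreatic Cancer"
      id: "NCIT:C168887"
  species:
    Human:
      code: HomSap
      stub_code: "01"
      label: "Homo sapiens"
      id: "NCBITaxon:9606"
      tax_code: MPH
    Mouse:
      code: MusMus
      stub_code: "02"
      label: "Mus musculus"
      id: "NCBITaxon:10090"
      tax_code: MRM
    Macaque:
      code: MacMul
      stub_code: "03"
      label: "Macaca mulatta"
      id: "NCBITaxon:9544"
      tax_code: MPM
    Zebrafish:
      code: DanRer
      stub_code: "04"
      label: "Danio rerio"
      id: "NCBITaxon:7955"
      tax_code: ARD
  tissue:
    Liver:
      code: LIV
      stub_code: "L"
      label: "Liver"
      id: "UBERON:0002107"
    Bone_marrow:
      code: BMR
      stub_code: "R"
      label: "Bone marrow"
      id: "UBERON:0002371"
    Brain:
      code: BRN
      stub_code: "N"
      label: "Brain"
      id: "UBERON:0000955"
    Lung:
      code: LNG
      stub_code: "U"
      label: "Lung"
      id: "UBERON:0002048"
    Kidney:
      code: KID
      stub_code: "K"
      label: "Kidney"
      id: "UBERON:0002113"
    Heart:
      code: HRT
      stub_code: "H"
      label: "Heart"
      id: "UBERON:0000948"
    Blood:
      code: BLD
      stub_code: "D"
      label: "Blood"
      id: "UBERON:0000178"
    Skin:
      code: SKN
      stub_code: "S"
      label: "Skin"
      id: "UBERON:0002097"
  sample_type:
    Tumor:
      code: TUM
      stub_code: "T"
      label: "Tumor tissue"
      id: "NCIT:C18009"
    Primary:
      code: PRI
      stub_code: "P"
      label: "Primary tumor site"
      id: "NCIT:C8509"
    Normal:
      code: NOR
      stub_code: "N"
      label: "Normal tissue"
      id: "NCIT:C14165"
    Metastasis:
      code: MET
      stub_code: "M"
      label: "Metastatic site"
      id: "NCIT:C19151"
    Cell_line:
      code: CLN
      stub_code: "C"
      label: "Cell line"
      id: "NCIT:C16403"
  assay:
    RNA_seq:
      code: RNA
      stub_code: "R"
      label: "RNA-seq"
      id: "EFO:0008896"
    DNA_seq:
      code: DNA
      stub_code: "D"
      label: "Targeted DNA sequencing"
      id: "EFO:0003738"
    WGS:
      code: WGS
      stub_code: "W"
      label: "Whole genome sequencing"
      id: "EFO:0003744"
    ATAC_seq:
      code: ATC
      stub_code: "A"
      label: "ATAC-seq"
      id: "EFO:0007045"
    Methylome:
      code: MTH
      stub_code: "M"
      label: "Methylation profiling"
      id: "EFO:0002759"
    Not_available:
      code: NAV
      stub_code: "n"
      label: "Assay not available"
  timepoint:
    Treatment:
      code: TRT
      stub_code: "T"
      label: "Treatment event"
      id: "NCIT:C25598"
    Collection:
      code: COL
      stub_code: "C"
      label: "Sample collection"
      id: "NCIT:C25453"
    Baseline:
      code: BSL
      stub_code: "B"
      label: "Baseline"
      id: "NCIT:C25213"
    Follow_up:
      code: FUP
      stub_code: "F"
      label: "Follow-up visit"
      id: "NCIT:C16033"
    Diagnosis:
      code: DGN
      stub_code: "G"
      label: "Diagnosis"
      id: "NCIT:C15220"
subject:
  # `study` is free form: any hyphen-free string is accepted in human
  # format and carried verbatim in stub format.
  type:
    Case:
      code: Case
      stub_code: "C"
      label: "Case"
      id: "NCIT:C49152"
    Control:
      code: Ctrl
      stub_code: "O"
      label: "Control"
      id: "NCIT:C28143"
    Relative:
      code: Rel
      stub_code: "R"
      label: "Relative of proband"
      id: "NCIT:C21480"
    Donor:
      code: Donor
      stub_code: "D"
      label: "Donor"
      id: "NCIT:C11307"
    Proband:
      code: Prob
      stub_code: "P"
      label: "Proband"
      id: "NCIT:C64435"
  sex:
    Male:
      code: Male
      stub_code: "M"
      label: "Male"
      id: "NCIT:C20197"
    Female:
      code: Female
      stub_code: "F"
      label: "Female"
      id: "NCIT:C16576"
    Other:
      code: Other
      stub_code: "O"
      label: "Other sex"
      id: "NCIT:C17998"
    Unknown:
      code: Unknown
      stub_code: "U"
      label: "Unknown sex"
      id: "NCIT:C17998"
    Not_reported:
      code: NRP
      stub_code: "N"
      label: "Sex not reported"
      id: "NCIT:C43234"
  age_group:
    A0_9:
      code: A0_9
      stub_code: "A0"
      label: "Aged 0-9 years"
    A10_19:
      code: A10_19
      stub_code: "A1"
      label: "Aged 10-19 years"
    A20_29:
      code: A20_29
      stub_code: "A2"
      label: "Aged 20-29 years"
    A30_39:
      code: A30_39
      stub_code: "A3"
      label: "Aged 30-39 years"
    A40_49:
      code: A40_49
      stub_code: "A4"
      label: "Aged 40-49 years"
    A50_59:
      code: A50_59
      stub_code: "A5"
      label: "Aged 50-59 years"
    A60_69:
      code: A60_69
      stub_code: "A6"
      label: "Aged 60-69 years"
    A70_79:
      code: A70_79
      stub_code: "A7"
      label: "Aged 70-79 years"
    A80_89:
      code: A80_89
      stub_code: "A8"
      label: "Aged 80-89 years"
    A90_99:
      code: A90_99
      stub_code: "A9"
      label: "Aged 90-99 years"
rules:
  subject_id: "^[0-9]{1,5}$"
  duration: "^P([0-9][DWMY]|0N)$"
  batch: "^[1-9][0-9]?$"
  replicate: "^[1-9][0-9]?$"
  condition: "^([A-Z][0-9]{2}(\\.[0-9]{1,2})?|NA)$"
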