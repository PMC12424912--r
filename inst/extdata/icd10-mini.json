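[
  {"code": "NA", "name": "not available"},
  {"code": "A41.9", "name": "sepsis, unspecified organism"},
  {"code": "B18.2", "name": "chronic viral hepatitis C"},
  {"code": "B20", "name": "human immunodeficiency virus disease"},
  {"code": "B34.9", "name": "viral infection, unspecified"},
  {"code": "C18.9", "name": "malignant neoplasm of colon, unspecified"},
  {"code": "C22.0", "name": "liver cell carcinoma"},
  {"code": "C22.1", "name": "intrahepatic bile duct carcinoma"},
  {"code": "C22.2", "name": "hepatoblastoma"},
  {"code": "C22.9", "name": "malignant neoplasm of liver, not specified as primary or secondary"},
  {"code": "C25.9", "name": "malignant neoplasm of pancreas, unspecified"},
  {"code": "C34.9", "name": "malignant neoplasm of unspecified part of bronchus or lung"},
  {"code": "C50.9", "name": "malignant neoplasm of breast of unspecified site"},
  {"code": "C61", "name": "malignant neoplasm of prostate"},
  {"code": "C64.9", "name": "malignant neoplasm of unspecified kidney, except renal pelvis"},
  {"code": "C71.9", "name": "malignant neoplasm of brain, unspecified"},
  {"code": "C91.0", "name": "acute lymphoblastic leukemia"},
  {"code": "C92.0", "name": "acute myeloblastic leukemia"},
  {"code": "C92.1", "name": "chronic myeloid leukemia, BCR/ABL-positive"},
  {"code": "D64.9", "name": "anemia, unspecified"},
  {"code": "E10.9", "name": "type 1 diabetes mellitus without complications"},
  {"code": "E11.9", "name": "type 2 diabetes mellitus without complications"},
  {"code": "E66.9", "name": "obesity, unspecified"},
  {"code": "E78.5", "name": "hyperlipidemia, unspecified"},
  {"code": "E84.9", "name": "cystic fibrosis, unspecified"},
  {"code": "F32.9", "name": "major depressive disorder, single episode, unspecified"},
  {"code": "G20", "name": "Parkinson disease"},
  {"code": "G30.9", "name": "Alzheimer disease, unspecified"},
  {"code": "G35", "name": "multiple sclerosis"},
  {"code": "G40.9", "name": "epilepsy, unspecified"},
  {"code": "I10", "name": "essential (primary) hypertension"},
  {"code": "I21.9", "name": "acute myocardial infarction, unspecified"},
  {"code": "I25.1", "name": "atherosclerotic heart disease of native coronary artery"},
  {"code": "I48.9", "name": "unspecified atrial fibrillation and atrial flutter"},
  {"code": "I50.9", "name": "heart failure, unspecified"},
  {"code": "J18.9", "name": "pneumonia, unspecified organism"},
  {"code": "J44.0", "name": "chronic obstructive pulmonary disease with acute lower respiratory infection"},
  {"code": "J44.1", "name": "chronic obstructive pulmonary disease with acute exacerbation"},
  {"code": "J44.9", "name": "chronic obstructive pulmonary disease, unspecified"},
  {"code": "J45.9", "name": "asthma, unspecified"},
  {"code": "J84.9", "name": "interstitial pulmonary disease, unspecified"},
  {"code": "K21.9", "name": "gastro-esophageal reflux disease without esophagitis"},
  {"code": "K70.3", "name": "alcoholic cirrhosis of liver"},
  {"code": "K74.6", "name": "other and unspecified cirrhosis of liver"},
  {"code": "K76.0", "name": "fatty (change of) liver, not elsewhere classified"},
  {"code": "M05.9", "name": "rheumatoid arthritis with rheumatoid factor, unspecified"},
  {"code": "M32.9", "name": "systemic lupus erythematosus, unspecified"},
  {"code": "N18.9", "name": "chronic kidney disease, unspecified"},
  {"code": "N39.0", "name": "urinary tract infection, site not specified"},
  {"code": "R50.9", "name": "fever, unspecified"}
]
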