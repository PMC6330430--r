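"id","syndrome","description","registry_version"
"B1","BRCA","Individual from a family with a known BRCA1/BRCA2 mutation","1.0"
"B2","BRCA","Personal history of breast cancer diagnosed <= 45 y","1.0"
"B3","BRCA","Breast cancer <= 50 y with an additional breast cancer primary","1.0"
"B4","BRCA","Breast cancer <= 50 y with >= 1 close blood relative with breast cancer","1.0"
"B5","BRCA","Breast cancer <= 50 y with >= 1 close blood relative with pancreatic cancer","1.0"
"B6","BRCA","Breast cancer <= 50 y with >= 1 close blood relative with prostate cancer","1.0"
"B7","BRCA","Breast cancer <= 50 y with an unknown or limited family history","1.0"
"B8","BRCA","Triple-negative breast cancer diagnosed <= 60 y","1.0"
"B9","BRCA","Breast cancer at any age with >= 2 close blood relatives with breast, pancreatic, or prostate cancer at any age","1.0"
"B10","BRCA","Breast cancer at any age with >= 1 close blood relative with breast cancer diagnosed <= 50 y","1.0"
"B11","BRCA","Breast cancer at any age with >= 1 close blood relative with ovarian carcinoma","1.0"
"B12","BRCA","Breast cancer at any age with a close male blood relative with breast cancer","1.0"
"B13","BRCA","Breast cancer at any age in an individual of ethnicity associated with higher mutation frequency (e.g., Ashkenazi Jewish)","1.0"
"B14","BRCA","Personal history of ovarian carcinoma (includes fallopian tube and primary peritoneal)","1.0"
"B15","BRCA","Personal history of male breast cancer","1.0"
"B16","BRCA","Personal history of prostate cancer (Gleason > 7) with qualifying family pattern","1.0"
"B17","BRCA","Personal history of pancreatic cancer with qualifying family pattern","1.0"
"B18","BRCA","First- or second-degree blood relative meeting any of the personal-history criteria","1.0"
"B19","BRCA","Third-degree relative with breast and/or ovarian carcinoma and >= 2 close blood relatives with breast cancer (at least one <= 50 y) and/or ovarian carcinoma","1.0"
"L1","LYNCH","Known Lynch syndrome mutation in the family","1.0"
"L2","LYNCH",">= 1 first-degree relative with colorectal or endometrial cancer diagnosed < 50 y","1.0"
"L3","LYNCH",">= 1 first-degree relative with colorectal or endometrial cancer and another synchronous or metachronous LS-related cancer","1.0"
"L4","LYNCH",">= 2 first- or second-degree relatives with LS-related cancer, including one diagnosed < 50 y","1.0"
"L5","LYNCH",">= 3 first- or second-degree relatives with LS-related cancer, regardless of age","1.0"
"L6","LYNCH","Family meets Amsterdam II criteria","1.0"
"P1","POLYPOSIS","Known APC/MUTYH mutation in the family","1.0"
"P2","POLYPOSIS","Personal cumulative adenoma count at or above threshold","1.0"
"P3","POLYPOSIS","First-degree relative with cumulative adenoma count at or above threshold","1.0"
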