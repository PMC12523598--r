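"parameter","specimen","platform","analyzer","mean_sigma","censored_ge6","available"
"Albumin","serum","Alinity c","Alinity c1",6,TRUE,TRUE
"Albumin","serum","Alinity c","Alinity c2",6,TRUE,TRUE
"Albumin","serum","Alinity c","Alinity c3",5.74,FALSE,TRUE
"Albumin","serum","Alinity c","Alinity c4",6,TRUE,TRUE
"AP","serum","Alinity c","Alinity c1",6,TRUE,TRUE
"AP","serum","Alinity c","Alinity c2",5.26,FALSE,TRUE
"AP","serum","Alinity c","Alinity c3",6,TRUE,TRUE
"AP","serum","Alinity c","Alinity c4",5.66,FALSE,TRUE
"ALT","serum","Alinity c","Alinity c1",6,TRUE,TRUE
"ALT","serum","Alinity c","Alinity c2",6,TRUE,TRUE
"ALT","serum","Alinity c","Alinity c3",6,TRUE,TRUE
"ALT","serum","Alinity c","Alinity c4",6,TRUE,TRUE
"Amylase","serum","Alinity c","Alinity c1",NA,FALSE,FALSE
"Amylase","serum","Alinity c","Alinity c2",5.39,FALSE,TRUE
"Amylase","serum","Alinity c","Alinity c3",5.9,FALSE,TRUE
"Amylase","serum","Alinity c","Alinity c4",NA,FALSE,FALSE
"AST","serum","Alinity c","Alinity c1",6,TRUE,TRUE
"AST","serum","Alinity c","Alinity c2",NA,FALSE,FALSE
"AST","serum","Alinity c","Alinity c3",4.38,FALSE,TRUE
"AST","serum","Alinity c","Alinity c4",5.52,FALSE,TRUE
"Calcium","serum","Alinity c","Alinity c1",6,TRUE,TRUE
"Calcium","serum","Alinity c","Alinity c2",5.82,FALSE,TRUE
"Calcium","serum","Alinity c","Alinity c3",5.14,FALSE,TRUE
"Calcium","serum","Alinity c","Alinity c4",5.82,FALSE,TRUE
"Cholesterol","serum","Alinity c","Alinity c1",NA,FALSE,FALSE
"Cholesterol","serum","Alinity c","Alinity c2",5.24,FALSE,TRUE
"Cholesterol","serum","Alinity c","Alinity c3",4.92,FALSE,TRUE
"Cholesterol","serum","Alinity c","Alinity c4",5.65,FALSE,TRUE
"Chloride","serum","Alinity c","Alinity c1",4.14,FALSE,TRUE
"Chloride","serum","Alinity c","Alinity c2",3.31,FALSE,TRUE
"Chloride","serum","Alinity c","Alinity c3",4.63,FALSE,TRUE
"Chloride","serum","Alinity c","Alinity c4",NA,FALSE,FALSE
"CK","serum","Alinity c","Alinity c1",NA,FALSE,FALSE
"CK","serum","Alinity c","Alinity c2",6,TRUE,TRUE
"CK","serum","Alinity c","Alinity c3",6,TRUE,TRUE
"CK","serum","Alinity c","Alinity c4",6,TRUE,TRUE
"Creatinine","serum","Alinity c","Alinity c1",6,TRUE,TRUE
"Creatinine","serum","Alinity c","Alinity c2",5,FALSE,TRUE
"Creatinine","serum","Alinity c","Alinity c3",5.42,FALSE,TRUE
"Creatinine","serum","Alinity c","Alinity c4",5.45,FALSE,TRUE
"Direct Bilirubin","serum","Alinity c","Alinity c1",5.15,FALSE,TRUE
"Direct Bilirubin","serum","Alinity c","Alinity c2",NA,FALSE,FALSE
"Direct Bilirubin","serum","Alinity c","Alinity c3",5.03,FALSE,TRUE
"Direct Bilirubin","serum","Alinity c","Alinity c4",NA,FALSE,FALSE
"GGT","serum","Alinity c","Alinity c1",6,TRUE,TRUE
"GGT","serum","Alinity c","Alinity c2",4.19,FALSE,TRUE
"GGT","serum","Alinity c","Alinity c3",6,TRUE,TRUE
"GGT","serum","Alinity c","Alinity c4",6,TRUE,TRUE
"Glucose","serum","Alinity c","Alinity c1",5.2,FALSE,TRUE
"Glucose","serum","Alinity c","Alinity c2",6,TRUE,TRUE
"Glucose","serum","Alinity c","Alinity c3",6,TRUE,TRUE
"Glucose","serum","Alinity c","Alinity c4",6,TRUE,TRUE
"HDL","serum","Alinity c","Alinity c1",NA,FALSE,FALSE
"HDL","serum","Alinity c","Alinity c2",NA,FALSE,FALSE
"HDL","serum","Alinity c","Alinity c3",NA,FALSE,FALSE
"HDL","serum","Alinity c","Alinity c4",4.43,FALSE,TRUE
"LD","serum","Alinity c","Alinity c1",3.69,FALSE,TRUE
"LD","serum","Alinity c","Alinity c2",NA,FALSE,FALSE
"LD","serum","Alinity c","Alinity c3",3.93,FALSE,TRUE
"LD","serum","Alinity c","Alinity c4",5.58,FALSE,TRUE
"Magnesium","serum","Alinity c","Alinity c1",3.39,FALSE,TRUE
"Magnesium","serum","Alinity c","Alinity c2",NA,FALSE,FALSE
"Magnesium","serum","Alinity c","Alinity c3",4.36,FALSE,TRUE
"Magnesium","serum","Alinity c","Alinity c4",4.68,FALSE,TRUE
"CRP","serum","Alinity c","Alinity c1",5,FALSE,TRUE
"CRP","serum","Alinity c","Alinity c2",5.83,FALSE,TRUE
"CRP","serum","Alinity c","Alinity c3",5.27,FALSE,TRUE
"CRP","serum","Alinity c","Alinity c4",5.86,FALSE,TRUE
"Potassium","serum","Alinity c","Alinity c1",5.94,FALSE,TRUE
"Potassium","serum","Alinity c","Alinity c2",5.91,FALSE,TRUE
"Potassium","serum","Alinity c","Alinity c3",6,TRUE,TRUE
"Potassium","serum","Alinity c","Alinity c4",NA,FALSE,FALSE
"Sodium","serum","Alinity c","Alinity c1",3.16,FALSE,TRUE
"Sodium","serum","Alinity c","Alinity c2",3.66,FALSE,TRUE
"Sodium","serum","Alinity c","Alinity c3",3.48,FALSE,TRUE
"Sodium","serum","Alinity c","Alinity c4",NA,FALSE,FALSE
"Total Bilirubin","serum","Alinity c","Alinity c1",6,TRUE,TRUE
"Total Bilirubin","serum","Alinity c","Alinity c2",6,TRUE,TRUE
"Total Bilirubin","serum","Alinity c","Alinity c3",6,TRUE,TRUE
"Total Bilirubin","serum","Alinity c","Alinity c4",6,TRUE,TRUE
"Total Protein","serum","Alinity c","Alinity c1",5.89,FALSE,TRUE
"Total Protein","serum","Alinity c","Alinity c2",4.05,FALSE,TRUE
"Total Protein","serum","Alinity c","Alinity c3",3.74,FALSE,TRUE
"Total Protein","serum","Alinity c","Alinity c4",5.39,FALSE,TRUE
"Triglyceride","serum","Alinity c","Alinity c1",6,TRUE,TRUE
"Triglyceride","serum","Alinity c","Alinity c2",NA,FALSE,FALSE
"Triglyceride","serum","Alinity c","Alinity c3",5.59,FALSE,TRUE
"Triglyceride","serum","Alinity c","Alinity c4",4.51,FALSE,TRUE
"Urea","serum","Alinity c","Alinity c1",6,TRUE,TRUE
"Urea","serum","Alinity c","Alinity c2",6,TRUE,TRUE
"Urea","serum","Alinity c","Alinity c3",5.11,FALSE,TRUE
"Urea","serum","Alinity c","Alinity c4",5.94,FALSE,TRUE
"Uric Acid","serum","Alinity c","Alinity c1",NA,FALSE,FALSE
"Uric Acid","serum","Alinity c","Alinity c2",5.18,FALSE,TRUE
"Uric Acid","serum","Alinity c","Alinity c3",4.47,FALSE,TRUE
"Uric Acid","serum","Alinity c","Alinity c4",NA,FALSE,FALSE
"Albumin U","urine","Alinity c","Alinity c1",NA,FALSE,FALSE
"Albumin U","urine","Alinity c","Alinity c2",6,TRUE,TRUE
"Albumin U","urine","Alinity c","Alinity c3",NA,FALSE,FALSE
"Albumin U","urine","Alinity c","Alinity c4",NA,FALSE,FALSE
"Calcium U","urine","Alinity c","Alinity c1",NA,FALSE,FALSE
"Calcium U","urine","Alinity c","Alinity c2",6,TRUE,TRUE
"Calcium U","urine","Alinity c","Alinity c3",NA,FALSE,FALSE
"Calcium U","urine","Alinity c","Alinity c4",NA,FALSE,FALSE
"Creatinine U","urine","Alinity c","Alinity c1",6,TRUE,TRUE
"Creatinine U","urine","Alinity c","Alinity c2",6,TRUE,TRUE
"Creatinine U","urine","Alinity c","Alinity c3",NA,FALSE,FALSE
"Creatinine U","urine","Alinity c","Alinity c4",NA,FALSE,FALSE
"Glucose U","urine","Alinity c","Alinity c1",NA,FALSE,FALSE
"Glucose U","urine","Alinity c","Alinity c2",6,TRUE,TRUE
"Glucose U","urine","Alinity c","Alinity c3",NA,FALSE,FALSE
"Glucose U","urine","Alinity c","Alinity c4",NA,FALSE,FALSE
"Phosphorus U","urine","Alinity c","Alinity c1",NA,FALSE,FALSE
"Phosphorus U","urine","Alinity c","Alinity c2",5.23,FALSE,TRUE
"Phosphorus U","urine","Alinity c","Alinity c3",NA,FALSE,FALSE
"Phosphorus U","urine","Alinity c","Alinity c4",NA,FALSE,FALSE
"Potassium U","urine","Alinity c","Alinity c1",6,TRUE,TRUE
"Potassium U","urine","Alinity c","Alinity c2",6,TRUE,TRUE
"Potassium U","urine","Alinity c","Alinity c3",NA,FALSE,FALSE
"Potassium U","urine","Alinity c","Alinity c4",NA,FALSE,FALSE
"Sodium U","urine","Alinity c","Alinity c1",6,TRUE,TRUE
"Sodium U","urine","Alinity c","Alinity c2",5.55,FALSE,TRUE
"Sodium U","urine","Alinity c","Alinity c3",NA,FALSE,FALSE
"Sodium U","urine","Alinity c","Alinity c4",NA,FALSE,FALSE
"Urea U","urine","Alinity c","Alinity c1",5.68,FALSE,TRUE
"Urea U","urine","Alinity c","Alinity c2",5.63,FALSE,TRUE
"Urea U","urine","Alinity c","Alinity c3",NA,FALSE,FALSE
"Urea U","urine","Alinity c","Alinity c4",NA,FALSE,FALSE
"NT-proBNP","serum","Cobas Pro","Cobas 1",4.97,FALSE,TRUE
"NT-proBNP","serum","Cobas Pro","Cobas 2",4.21,FALSE,TRUE
"Procalcitonin","serum","Cobas Pro","Cobas 1",6,TRUE,TRUE
"Procalcitonin","serum","Cobas Pro","Cobas 2",4.91,FALSE,TRUE
"Troponin T","serum","Cobas Pro","Cobas 1",6,TRUE,TRUE
"Troponin T","serum","Cobas Pro","Cobas 2",6,TRUE,TRUE
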