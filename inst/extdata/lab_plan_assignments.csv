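"parameter","platform","analyzer","plan_id","category","status"
"Albumin","Alinity c","Alinity c1",1,"B","ok"
"Albumin","Alinity c","Alinity c2",1,"C","ok"
"Albumin","Alinity c","Alinity c3",1,"C","ok"
"Albumin","Alinity c","Alinity c4",1,"D","ok"
"AP","Alinity c","Alinity c1",1,"B","ok"
"AP","Alinity c","Alinity c2",1,"C","ok"
"AP","Alinity c","Alinity c3",1,"C","ok"
"AP","Alinity c","Alinity c4",1,"D","ok"
"ALT","Alinity c","Alinity c1",1,"B","ok"
"ALT","Alinity c","Alinity c2",1,"B","ok"
"ALT","Alinity c","Alinity c3",1,"C","ok"
"ALT","Alinity c","Alinity c4",1,"D","ok"
"Amylase","Alinity c","Alinity c1",NA,NA,"not_available"
"Amylase","Alinity c","Alinity c2",1,"D","ok"
"Amylase","Alinity c","Alinity c3",1,"E","ok"
"Amylase","Alinity c","Alinity c4",NA,NA,"not_available"
"AST","Alinity c","Alinity c1",1,"C","ok"
"AST","Alinity c","Alinity c2",NA,NA,"not_available"
"AST","Alinity c","Alinity c3",4,"C","ok"
"AST","Alinity c","Alinity c4",1,"D","ok"
"Calcium","Alinity c","Alinity c1",1,"B","ok"
"Calcium","Alinity c","Alinity c2",1,"C","ok"
"Calcium","Alinity c","Alinity c3",3,"C","ok"
"Calcium","Alinity c","Alinity c4",1,"D","ok"
"Cholesterol","Alinity c","Alinity c1",NA,NA,"not_available"
"Cholesterol","Alinity c","Alinity c2",1,"C","ok"
"Cholesterol","Alinity c","Alinity c3",3,"E","ok"
"Cholesterol","Alinity c","Alinity c4",1,"D","ok"
"Chloride","Alinity c","Alinity c1",4,"E","ok"
"Chloride","Alinity c","Alinity c2",NA,"E","not_controllable"
"Chloride","Alinity c","Alinity c3",7,"E","ok"
"Chloride","Alinity c","Alinity c4",NA,NA,"not_available"
"CK","Alinity c","Alinity c1",NA,NA,"not_available"
"CK","Alinity c","Alinity c2",1,"D","ok"
"CK","Alinity c","Alinity c3",1,"E","ok"
"CK","Alinity c","Alinity c4",1,"E","ok"
"Creatinine","Alinity c","Alinity c1",1,"A","ok"
"Creatinine","Alinity c","Alinity c2",5,"B","ok"
"Creatinine","Alinity c","Alinity c3",1,"C","ok"
"Creatinine","Alinity c","Alinity c4",1,"C","ok"
"Direct Bilirubin","Alinity c","Alinity c1",2,"E","ok"
"Direct Bilirubin","Alinity c","Alinity c2",NA,NA,"not_available"
"Direct Bilirubin","Alinity c","Alinity c3",3,"E","ok"
"Direct Bilirubin","Alinity c","Alinity c4",NA,NA,"not_available"
"GGT","Alinity c","Alinity c1",1,"B","ok"
"GGT","Alinity c","Alinity c2",6,"C","ok"
"GGT","Alinity c","Alinity c3",1,"C","ok"
"GGT","Alinity c","Alinity c4",1,"D","ok"
"Glucose","Alinity c","Alinity c1",1,"B","ok"
"Glucose","Alinity c","Alinity c2",1,"B","ok"
"Glucose","Alinity c","Alinity c3",1,"C","ok"
"Glucose","Alinity c","Alinity c4",1,"D","ok"
"HDL","Alinity c","Alinity c1",NA,NA,"not_available"
"HDL","Alinity c","Alinity c2",NA,NA,"not_available"
"HDL","Alinity c","Alinity c3",NA,NA,"not_available"
"HDL","Alinity c","Alinity c4",4,"D","ok"
"LD","Alinity c","Alinity c1",NA,"C","not_controllable"
"LD","Alinity c","Alinity c2",NA,NA,"not_available"
"LD","Alinity c","Alinity c3",NA,"E","not_controllable"
"LD","Alinity c","Alinity c4",1,"E","ok"
"Magnesium","Alinity c","Alinity c1",NA,"C","not_controllable"
"Magnesium","Alinity c","Alinity c2",NA,NA,"not_available"
"Magnesium","Alinity c","Alinity c3",4,"E","ok"
"Magnesium","Alinity c","Alinity c4",7,"E","ok"
"CRP","Alinity c","Alinity c1",3,"C","ok"
"CRP","Alinity c","Alinity c2",1,"C","ok"
"CRP","Alinity c","Alinity c3",2,"C","ok"
"CRP","Alinity c","Alinity c4",1,"D","ok"
"Potassium","Alinity c","Alinity c1",1,"B","ok"
"Potassium","Alinity c","Alinity c2",1,"B","ok"
"Potassium","Alinity c","Alinity c3",1,"A","ok"
"Potassium","Alinity c","Alinity c4",NA,NA,"not_available"
"Sodium","Alinity c","Alinity c1",NA,"B","not_controllable"
"Sodium","Alinity c","Alinity c2",NA,"B","not_controllable"
"Sodium","Alinity c","Alinity c3",NA,"A","not_controllable"
"Sodium","Alinity c","Alinity c4",NA,NA,"not_available"
"Total Bilirubin","Alinity c","Alinity c1",1,"B","ok"
"Total Bilirubin","Alinity c","Alinity c2",1,"C","ok"
"Total Bilirubin","Alinity c","Alinity c3",1,"C","ok"
"Total Bilirubin","Alinity c","Alinity c4",1,"D","ok"
"Total Protein","Alinity c","Alinity c1",1,"C","ok"
"Total Protein","Alinity c","Alinity c2",6,"C","ok"
"Total Protein","Alinity c","Alinity c3",NA,"C","not_controllable"
"Total Protein","Alinity c","Alinity c4",2,"D","ok"
"Triglyceride","Alinity c","Alinity c1",1,"C","ok"
"Triglyceride","Alinity c","Alinity c2",NA,NA,"not_available"
"Triglyceride","Alinity c","Alinity c3",1,"E","ok"
"Triglyceride","Alinity c","Alinity c4",4,"D","ok"
"Urea","Alinity c","Alinity c1",1,"A","ok"
"Urea","Alinity c","Alinity c2",1,"A","ok"
"Urea","Alinity c","Alinity c3",3,"C","ok"
"Urea","Alinity c","Alinity c4",1,"C","ok"
"Uric Acid","Alinity c","Alinity c1",NA,NA,"not_available"
"Uric Acid","Alinity c","Alinity c2",2,"E","ok"
"Uric Acid","Alinity c","Alinity c3",7,"E","ok"
"Uric Acid","Alinity c","Alinity c4",NA,NA,"not_available"
"Albumin U","Alinity c","Alinity c1",NA,NA,"not_available"
"Albumin U","Alinity c","Alinity c2",1,"D","ok"
"Albumin U","Alinity c","Alinity c3",NA,NA,"not_available"
"Albumin U","Alinity c","Alinity c4",NA,NA,"not_available"
"Calcium U","Alinity c","Alinity c1",NA,NA,"not_available"
"Calcium U","Alinity c","Alinity c2",1,"E","ok"
"Calcium U","Alinity c","Alinity c3",NA,NA,"not_available"
"Calcium U","Alinity c","Alinity c4",NA,NA,"not_available"
"Creatinine U","Alinity c","Alinity c1",1,"E","ok"
"Creatinine U","Alinity c","Alinity c2",1,"E","ok"
"Creatinine U","Alinity c","Alinity c3",NA,NA,"not_available"
"Creatinine U","Alinity c","Alinity c4",NA,NA,"not_available"
"Glucose U","Alinity c","Alinity c1",NA,NA,"not_available"
"Glucose U","Alinity c","Alinity c2",1,"E","ok"
"Glucose U","Alinity c","Alinity c3",NA,NA,"not_available"
"Glucose U","Alinity c","Alinity c4",NA,NA,"not_available"
"Phosphorus U","Alinity c","Alinity c1",NA,NA,"not_available"
"Phosphorus U","Alinity c","Alinity c2",1,"E","ok"
"Phosphorus U","Alinity c","Alinity c3",NA,NA,"not_available"
"Phosphorus U","Alinity c","Alinity c4",NA,NA,"not_available"
"Potassium U","Alinity c","Alinity c1",1,"E","ok"
"Potassium U","Alinity c","Alinity c2",1,"E","ok"
"Potassium U","Alinity c","Alinity c3",NA,NA,"not_available"
"Potassium U","Alinity c","Alinity c4",NA,NA,"not_available"
"Sodium U","Alinity c","Alinity c1",1,"E","ok"
"Sodium U","Alinity c","Alinity c2",1,"E","ok"
"Sodium U","Alinity c","Alinity c3",NA,NA,"not_available"
"Sodium U","Alinity c","Alinity c4",NA,NA,"not_available"
"Urea U","Alinity c","Alinity c1",1,"E","ok"
"Urea U","Alinity c","Alinity c2",1,"E","ok"
"Urea U","Alinity c","Alinity c3",NA,NA,"not_available"
"Urea U","Alinity c","Alinity c4",NA,NA,"not_available"
"NT-proBNP","Cobas Pro","Cobas 1",3,"D","ok"
"NT-proBNP","Cobas Pro","Cobas 2",4,"D","ok"
"Procalcitonin","Cobas Pro","Cobas 1",1,"E","ok"
"Procalcitonin","Cobas Pro","Cobas 2",3,"E","ok"
"Troponin T","Cobas Pro","Cobas 1",1,"D","ok"
"Troponin T","Cobas Pro","Cobas 2",1,"D","ok"
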