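"source_code","source_description","source_context","target_concept_id","mapping_status"
"1","Inpatient stay","visit","9201","APPROVED"
"2","Outpatient in hospital","visit","2004000001","APPROVED"
"3","Ambulatory clinic or center","visit","2004000002","APPROVED"
"V","Full stationary stay","visit","9201","APPROVED"
"T","Partial stationary stay","visit","2004000003","APPROVED"
"AMB","Ambulatory case","visit","9202","APPROVED"
"NOTFALL","Ambulatory emergency case","visit","9203","APPROVED"
"DENT","Dental case","visit","2004000004","APPROVED"
"H","Primary diagnosis","condition_status","32902","APPROVED"
"N","Secondary diagnosis","condition_status","32908","APPROVED"
"A","Admission diagnosis","condition_status","32890","APPROVED"
"G","Confirmed diagnosis","condition_status","32893","APPROVED"
"V","Preliminary diagnosis","condition_status","2003000001","APPROVED"
"Z","Resolved diagnosis","condition_status","2003000002","APPROVED"
"COPD","COPD disease management program","dmp","4233538","APPROVED"
"DM2","Type 2 diabetes disease management program","dmp","4193416","APPROVED"
"KHK","Coronary heart disease management program","dmp","4233538","UNCHECKED"
"01","General practitioner","specialty","38004446","APPROVED"
"02","Internal medicine","specialty","38004446","APPROVED"
"03","Cardiologist","specialty","38004451","APPROVED"
"04","Angiology","specialty","38004451","APPROVED"
"05","Dermatologist","specialty","38004452","APPROVED"
"06","Allergology","specialty","38004452","APPROVED"
"07","Neurologist","specialty","38004453","APPROVED"
"08","Psychiatry","specialty","38004453","APPROVED"
"10","Dentist","specialty","38004455","APPROVED"
"11","Orthodontist","specialty","38004455","APPROVED"
"12","Pediatrics","specialty","38004446","APPROVED"
"13","Gynecology","specialty","38004446","APPROVED"
"14","Urology","specialty","38004446","APPROVED"
"1","Dental restoration group","dental_group","4042673","APPROVED"
"2","Dental prophylaxis group","dental_group","4159251","APPROVED"
"3","Dental surgery group","dental_group","4163273","APPROVED"
"4","Endodontic treatment group","dental_group","4193783","APPROVED"
"5","Dental prosthetics group","dental_group","4082281","APPROVED"
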