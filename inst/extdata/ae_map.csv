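icd9_code,ae_category,label
787.01,1,nausea and vomiting
787.02,1,nausea alone
536.2,1,persistent vomiting
787.91,2,diarrhea
564.5,2,functional diarrhea
558.9,2,noninfectious gastroenteritis
564.00,3,constipation unspecified
564.01,3,slow transit constipation
560.1,3,paralytic ileus
528.00,4,stomatitis
528.09,4,oral mucositis
478.11,4,nasopharyngeal mucositis
288.00,5,neutropenia unspecified
288.03,5,drug-induced neutropenia
038.9,5,septicemia
285.9,6,anemia unspecified
285.3,6,antineoplastic-induced anemia
280.9,6,iron deficiency anemia
287.5,7,thrombocytopenia unspecified
287.4,7,secondary thrombocytopenia
459.0,7,hemorrhage unspecified
780.61,8,fever with neutropenia
780.60,8,fever unspecified
790.7,8,bacteremia
357.6,9,drug-induced polyneuropathy
356.9,9,peripheral neuropathy
355.9,9,mononeuritis unspecified
780.79,10,fatigue and malaise
799.3,10,debility unspecified
780.71,10,chronic fatigue
276.51,11,dehydration
276.8,11,hypokalemia
276.1,11,hyponatremia
425.4,12,cardiomyopathy
428.0,12,congestive heart failure
427.31,12,atrial fibrillation
453.40,13,deep vein thrombosis
415.19,13,pulmonary embolism
451.9,13,thrombophlebitis
573.3,14,hepatitis unspecified
790.4,14,elevated transaminases
572.2,14,hepatic encephalopathy
584.9,15,acute kidney failure
583.9,15,nephropathy unspecified
588.9,15,impaired renal function
693.0,16,drug dermatitis
704.00,16,alopecia
782.1,16,rash and eruption
338.3,17,neoplasm-related pain
724.5,17,backache
719.45,17,joint pain
311,18,depressive disorder
300.00,18,anxiety state
780.52,18,insomnia
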