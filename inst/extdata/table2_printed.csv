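group,stratum,n,users,mono,poly
one_diagnosis,Substance use disorders,16,8,6,2
one_diagnosis,Schizophrenia and other psychosis,101,101,62,39
one_diagnosis,Mood disorders,69,51,33,18
one_diagnosis,Anxiety-related disorders,24,5,4,1
one_diagnosis,Personality disorders,21,12,10,2
one_diagnosis,Rest of the diagnoses,12,0,0,0
comorbidity,Organic disorders + mood disorders,5,2,1,1
comorbidity,Substance use disorders + schizophrenia and other psychosis,10,9,4,5
comorbidity,Substance use disorders + mood disorders,6,6,4,2
comorbidity,Substance use disorders + personality disorders,7,9,4,5
comorbidity,Schizophrenia and other psychosis + personality disorders,7,6,3,3
comorbidity,Mood disorders + personality disorders,6,4,2,2
comorbidity,Anxiety-related disorders + personality disorders,9,4,4,0
comorbidity,Other combinations,60,0,0,0
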