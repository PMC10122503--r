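outcome,type,value
overall,icd,T81
overall,icd,T84
overall,icd,I21
overall,icd,I22
overall,icd,I26
overall,icd,I46
overall,icd,I61
overall,icd,I63
overall,icd,I80
overall,icd,R57
overall,icd,K65
overall,icd,K91
overall,icd,J95
overall,icd,J96
overall,icd,J15
overall,icd,A41
overall,icd,A49
overall,icd,N17
overall,icd,N39
overall,icd,G93
overall,event,death
overall,event,reoperation
overall,event,readmission
overall,event,icu_or_ventilation
critical,icd,I21
critical,icd,I22
critical,icd,R57
critical,icd,I63
critical,icd,I26
critical,icd,K65
critical,event,death
critical,event,icu_or_ventilation
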