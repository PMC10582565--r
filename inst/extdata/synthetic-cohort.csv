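study_id,modality,indicator,region_a,region_b,direction,raw_r,n_patients,n_controls
S01,MRI,FC,Tha,VC,1,,25,20
S01,MRI,FC,Tha,BG,-1,,25,20
S02,MRI,ReHo,Cere,Tha,,0.42,28,25
S03,MEG,FC,SMA,BG,1,,30,24
S04,MRI,gFCD,PFC,SMA,-1,,35,30
S05,MRI+EEG,FC,Cere,BG,,-0.31,40,35
S06,EEG,EC,PFC,Tha,-1,,22,18
S07,MRI,FC,VC,Cere,1,,31,26
S08,MRI,lFCD,SMC,SMA,1,,29,24
S09,MRI,FC,Hipp,Tha,-1,,33,28
S10,MRI+DTI,SC,BG,PFC,,0.27,27,22
S11,MRI,FC,STG,MTG,1,,36,30
S12,MRI,ReHo,Ins,pACC,-1,,24,20
S13,MEG,FC,SFG,PFC,,-0.55,32,27
S14,MRI,FC,Prec,VC,1,,38,33
S15,MRI,FC,Cere,SMA,-1,,32,25
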