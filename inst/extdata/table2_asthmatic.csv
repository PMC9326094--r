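subject_id,group_label,labored_breathing,abnormal_auscultation,mucus_score,tracheal_neut_gt20,wcs,macrophages,lymphocytes,neutrophils,eosinophils,mast_cells
S01,severe,true,false,4,true,10,42,33,24,0,1
S02,severe,false,true,5,true,9,27.5,30.5,40,0,2
S03,severe,true,true,5,true,23,4,4,92,0,0
S04,severe,true,true,4,true,14,26.5,50.5,14,0,9
S05,severe,true,false,2,true,7,54,24,20,0,2
S06,severe,false,false,3,true,6,34,23,43,0,0
S07,severe,true,false,3,true,8,39,25,35,0,1
S08,severe,true,false,4,true,5,22,29,49,0,3
S09,severe,false,true,4,true,6,23,47.5,28,0,1.5
S10,severe,false,true,5,true,13,17,10,73,0,0
S11,severe,true,false,4,true,6,34.5,22.5,42,0,1
S12,severe,false,true,5,true,8,34.5,18,46,0,1.5
S13,severe,true,false,3,true,5,30,44,25,0,1
S14,severe,false,false,3,,4,19,57,24,0,0
M01,moderate,false,false,2,false,0,33.5,60.5,1.5,0,4.5
M02,moderate,false,false,2,false,0,34.5,48,15,0,2.5
M03,moderate,false,false,2,false,2,68,27,1,0,4
M04,moderate,false,false,2,false,3,51,28,19,0,2
M05,moderate,false,false,2,true,0,42.5,40,14,0,3.5
M06,moderate,false,false,3,true,1,45.5,46,8,0.5,0
M07,moderate,false,false,2,false,2,55,39,1,1.5,3.5
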