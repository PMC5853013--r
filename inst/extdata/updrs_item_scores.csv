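subject_id,task,item,side,state,score
S01,finger_tapping,23,tested,OFF,3
S01,finger_tapping,23,tested,ON,3
S02,finger_tapping,23,tested,OFF,2
S02,finger_tapping,23,tested,ON,1
S03,finger_tapping,23,tested,OFF,1
S03,finger_tapping,23,tested,ON,0
S04,finger_tapping,23,tested,OFF,2
S04,finger_tapping,23,tested,ON,1
S05,finger_tapping,23,tested,OFF,1
S05,finger_tapping,23,tested,ON,1
S06,finger_tapping,23,tested,OFF,3
S06,finger_tapping,23,tested,ON,2
S07,finger_tapping,23,tested,OFF,1
S07,finger_tapping,23,tested,ON,0
S08,finger_tapping,23,tested,OFF,3
S08,finger_tapping,23,tested,ON,2
S09,finger_tapping,23,tested,OFF,2
S09,finger_tapping,23,tested,ON,1
S10,finger_tapping,23,tested,OFF,1
S10,finger_tapping,23,tested,ON,1
S11,finger_tapping,23,tested,OFF,2
S11,finger_tapping,23,tested,ON,1
S12,finger_tapping,23,tested,OFF,2
S12,finger_tapping,23,tested,ON,1
S13,finger_tapping,23,tested,OFF,1
S13,finger_tapping,23,tested,ON,1
S14,finger_tapping,23,tested,OFF,3
S14,finger_tapping,23,tested,ON,2
S01,pronosupination,25,tested,OFF,2
S01,pronosupination,25,tested,ON,2
S02,pronosupination,25,tested,OFF,1
S02,pronosupination,25,tested,ON,1
S03,pronosupination,25,tested,OFF,1
S03,pronosupination,25,tested,ON,0
S04,pronosupination,25,tested,OFF,2
S04,pronosupination,25,tested,ON,1
S05,pronosupination,25,tested,OFF,1
S05,pronosupination,25,tested,ON,1
S06,pronosupination,25,tested,OFF,4
S06,pronosupination,25,tested,ON,4
S07,pronosupination,25,tested,OFF,1
S07,pronosupination,25,tested,ON,0
S08,pronosupination,25,tested,OFF,2
S08,pronosupination,25,tested,ON,2
S09,pronosupination,25,tested,OFF,1
S09,pronosupination,25,tested,ON,1
S10,pronosupination,25,tested,OFF,1
S10,pronosupination,25,tested,ON,1
S11,pronosupination,25,tested,OFF,1
S11,pronosupination,25,tested,ON,0
S12,pronosupination,25,tested,OFF,2
S12,pronosupination,25,tested,ON,1
S13,pronosupination,25,tested,OFF,1
S13,pronosupination,25,tested,ON,1
S14,pronosupination,25,tested,OFF,1
S14,pronosupination,25,tested,ON,1
S01,rigidity,22,right,OFF,2
S01,rigidity,22,right,ON,2
S01,rigidity,22,left,OFF,2
S01,rigidity,22,left,ON,2
S02,rigidity,22,right,OFF,2
S02,rigidity,22,right,ON,1
S02,rigidity,22,left,OFF,2
S02,rigidity,22,left,ON,1
S03,rigidity,22,right,OFF,2
S03,rigidity,22,right,ON,2
S03,rigidity,22,left,OFF,2
S03,rigidity,22,left,ON,2
S04,rigidity,22,right,OFF,2
S04,rigidity,22,right,ON,1
S04,rigidity,22,left,OFF,1
S04,rigidity,22,left,ON,1
S05,rigidity,22,right,OFF,2
S05,rigidity,22,right,ON,1
S05,rigidity,22,left,OFF,2
S05,rigidity,22,left,ON,2
S06,rigidity,22,right,OFF,2
S06,rigidity,22,right,ON,2
S06,rigidity,22,left,OFF,2
S06,rigidity,22,left,ON,2
S07,rigidity,22,right,OFF,1
S07,rigidity,22,right,ON,0
S07,rigidity,22,left,OFF,1
S07,rigidity,22,left,ON,1
S08,rigidity,22,right,OFF,2
S08,rigidity,22,right,ON,2
S08,rigidity,22,left,OFF,3
S08,rigidity,22,left,ON,2
S09,rigidity,22,right,OFF,0
S09,rigidity,22,right,ON,0
S09,rigidity,22,left,OFF,0
S09,rigidity,22,left,ON,0
S10,rigidity,22,right,OFF,2
S10,rigidity,22,right,ON,1
S10,rigidity,22,left,OFF,2
S10,rigidity,22,left,ON,1
S11,rigidity,22,right,OFF,1
S11,rigidity,22,right,ON,1
S11,rigidity,22,left,OFF,2
S11,rigidity,22,left,ON,1
S12,rigidity,22,right,OFF,1
S12,rigidity,22,right,ON,1
S12,rigidity,22,left,OFF,2
S12,rigidity,22,left,ON,2
S13,rigidity,22,right,OFF,1
S13,rigidity,22,right,ON,1
S13,rigidity,22,left,OFF,2
S13,rigidity,22,left,ON,1
S14,rigidity,22,right,OFF,2
S14,rigidity,22,right,ON,2
S14,rigidity,22,left,OFF,1
S14,rigidity,22,left,ON,1
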