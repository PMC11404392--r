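provider_id,quarter,division,specialty,m1_rx_count,m2_patient_count,m3_gt5day,m4_gt50medd,m5_gt90medd
P1,2021Q3,Metro,EM,1,1,0,0,0
P2,2021Q3,Metro,EM,2,2,0,0,0
P3,2021Q3,Metro,EM,3,3,2,1,0
P4,2021Q3,Metro,EM,6,4,1,1,1
P5,2021Q3,Metro,EM,20,10,0,0,0
P6,2021Q3,Metro,IM,0,0,0,0,0
P7,2021Q3,Metro,IM,1,1,0,0,0
P8,2021Q3,Metro,IM,1,1,1,0,0
P9,2021Q3,Metro,IM,2,2,0,0,0
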