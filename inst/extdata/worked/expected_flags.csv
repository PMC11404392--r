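provider_id,metric,status
P1,m1_rx_count,within
P1,m2_patient_count,within
P1,m3_gt5day,within
P1,m4_gt50medd,within
P1,m5_gt90medd,within
P2,m1_rx_count,within
P2,m2_patient_count,within
P2,m3_gt5day,within
P2,m4_gt50medd,within
P2,m5_gt90medd,within
P3,m1_rx_count,within
P3,m2_patient_count,within
P3,m3_gt5day,outlier
P3,m4_gt50medd,within
P3,m5_gt90medd,within
P4,m1_rx_count,within
P4,m2_patient_count,outlier
P4,m3_gt5day,within
P4,m4_gt50medd,within
P4,m5_gt90medd,extreme_outlier
P5,m1_rx_count,extreme_outlier
P5,m2_patient_count,extreme_outlier
P5,m3_gt5day,within
P5,m4_gt50medd,within
P5,m5_gt90medd,within
P6,m1_rx_count,within
P6,m2_patient_count,within
P6,m3_gt5day,within
P6,m4_gt50medd,within
P6,m5_gt90medd,within
P7,m1_rx_count,outlier
P7,m2_patient_count,outlier
P7,m3_gt5day,within
P7,m4_gt50medd,within
P7,m5_gt90medd,within
P8,m1_rx_count,outlier
P8,m2_patient_count,outlier
P8,m3_gt5day,outlier
P8,m4_gt50medd,within
P8,m5_gt90medd,within
P9,m1_rx_count,outlier
P9,m2_patient_count,outlier
P9,m3_gt5day,within
P9,m4_gt50medd,within
P9,m5_gt90medd,within
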