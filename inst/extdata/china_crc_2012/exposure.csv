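factor,sex,region,level,prevalence,rr,rr_lo,rr_hi,is_reference,lower_bound
tobacco_smoking,male,national,ever_smoker,0.574,1.16,1.09,1.24,FALSE,NA
tobacco_smoking,male,national,never_smoker,0.426,1,1,1,TRUE,NA
tobacco_smoking,female,national,ever_smoker,0.026,1.16,1.09,1.24,FALSE,NA
tobacco_smoking,female,national,never_smoker,0.974,1,1,1,TRUE,NA
alcohol_drinking,male,national,drinker,0.396,1.24,1.01,1.54,FALSE,NA
alcohol_drinking,male,national,non_drinker,0.604,1,1,1,TRUE,NA
alcohol_drinking,female,national,drinker,0.045,1.24,1.01,1.54,FALSE,NA
alcohol_drinking,female,national,non_drinker,0.955,1,1,1,TRUE,NA
overweight_obesity,male,national,overweight,0.1503,1.25,1.07,1.45,FALSE,NA
overweight_obesity,male,national,obese,0.0249,1.57,1.23,2.00,FALSE,NA
overweight_obesity,male,national,normal_weight,0.8248,1,1,1,TRUE,NA
overweight_obesity,female,national,overweight,0.1697,1.25,1.07,1.45,FALSE,NA
overweight_obesity,female,national,obese,0.0341,1.57,1.23,2.00,FALSE,NA
overweight_obesity,female,national,normal_weight,0.7962,1,1,1,TRUE,NA
physical_inactivity,male,national,inactive,0.304,1.32,1.23,1.41,FALSE,NA
physical_inactivity,male,national,active,0.696,1,1,1,TRUE,NA
physical_inactivity,female,national,inactive,0.368,1.27,1.17,1.41,FALSE,NA
physical_inactivity,female,national,active,0.632,1,1,1,TRUE,NA
low_vegetable_intake,male,urban,Q1,0.2,1.52,1.14,1.95,FALSE,0
low_vegetable_intake,male,urban,Q2,0.2,1.30,1.09,1.51,FALSE,166.7
low_vegetable_intake,male,urban,Q3,0.2,1.20,1.06,1.34,FALSE,250.0
low_vegetable_intake,male,urban,Q4,0.2,1.12,1.04,1.19,FALSE,325.0
low_vegetable_intake,male,urban,Q5,0.2,1,1,1,TRUE,441.7
low_vegetable_intake,male,rural,Q1,0.2,1.50,1.14,1.92,FALSE,0
low_vegetable_intake,male,rural,Q2,0.2,1.30,1.09,1.52,FALSE,155.0
low_vegetable_intake,male,rural,Q3,0.2,1.21,1.06,1.35,FALSE,233.3
low_vegetable_intake,male,rural,Q4,0.2,1.12,1.04,1.19,FALSE,316.7
low_vegetable_intake,male,rural,Q5,0.2,1,1,1,TRUE,433.3
low_vegetable_intake,female,urban,Q1,0.2,1.46,1.13,1.83,FALSE,0
low_vegetable_intake,female,urban,Q2,0.2,1.27,1.08,1.46,FALSE,150.0
low_vegetable_intake,female,urban,Q3,0.2,1.18,1.05,1.30,FALSE,225.0
low_vegetable_intake,female,urban,Q4,0.2,1.10,1.03,1.16,FALSE,300.0
low_vegetable_intake,female,urban,Q5,0.2,1,1,1,TRUE,400.0
low_vegetable_intake,female,rural,Q1,0.2,1.46,1.13,1.83,FALSE,0
low_vegetable_intake,female,rural,Q2,0.2,1.27,1.08,1.46,FALSE,150.0
low_vegetable_intake,female,rural,Q3,0.2,1.19,1.06,1.31,FALSE,220.0
low_vegetable_intake,female,rural,Q4,0.2,1.10,1.03,1.16,FALSE,300.0
low_vegetable_intake,female,rural,Q5,0.2,1,1,1,TRUE,400.0
low_fruit_intake,male,urban,Q1,0.2,1.12,1.04,1.21,FALSE,0
low_fruit_intake,male,urban,Q2,0.2,1.09,1.03,1.15,FALSE,50.0
low_fruit_intake,male,urban,Q3,0.2,1.06,1.02,1.11,FALSE,83.3
low_fruit_intake,male,urban,Q4,0.2,1.04,1.01,1.07,FALSE,116.7
low_fruit_intake,male,urban,Q5,0.2,1,1,1,TRUE,183.3
low_fruit_intake,male,rural,Q1,0.2,1.12,1.04,1.20,FALSE,0
low_fruit_intake,male,rural,Q2,0.2,1.09,1.03,1.16,FALSE,33.3
low_fruit_intake,male,rural,Q3,0.2,1.07,1.02,1.12,FALSE,66.7
low_fruit_intake,male,rural,Q4,0.2,1.06,1.02,1.10,FALSE,88.3
low_fruit_intake,male,rural,Q5,0.2,1,1,1,TRUE,176.7
low_fruit_intake,female,urban,Q1,0.2,1.13,1.04,1.23,FALSE,0
low_fruit_intake,female,urban,Q2,0.2,1.10,1.03,1.17,FALSE,50.0
low_fruit_intake,female,urban,Q3,0.2,1.07,1.02,1.13,FALSE,83.3
low_fruit_intake,female,urban,Q4,0.2,1.05,1.02,1.09,FALSE,116.7
low_fruit_intake,female,urban,Q5,0.2,1,1,1,TRUE,200.0
low_fruit_intake,female,rural,Q1,0.2,1.16,1.05,1.28,FALSE,0
low_fruit_intake,female,rural,Q2,0.2,1.13,1.04,1.23,FALSE,33.3
low_fruit_intake,female,rural,Q3,0.2,1.11,1.03,1.19,FALSE,66.7
low_fruit_intake,female,rural,Q4,0.2,1.09,1.03,1.15,FALSE,100.0
low_fruit_intake,female,rural,Q5,0.2,1,1,1,TRUE,233.3
high_red_processed_meat_intake,male,urban,Q1,0.2,1,1,1,TRUE,0
high_red_processed_meat_intake,male,urban,Q2,0.2,1.07,1.02,1.11,FALSE,50.0
high_red_processed_meat_intake,male,urban,Q3,0.2,1.12,1.03,1.20,FALSE,83.3
high_red_processed_meat_intake,male,urban,Q4,0.2,1.17,1.05,1.29,FALSE,120.0
high_red_processed_meat_intake,male,urban,Q5,0.2,1.27,1.07,1.48,FALSE,183.3
high_red_processed_meat_intake,male,rural,Q1,0.2,1,1,1,TRUE,0
high_red_processed_meat_intake,male,rural,Q2,0.2,1.04,1.01,1.07,FALSE,33.3
high_red_processed_meat_intake,male,rural,Q3,0.2,1.08,1.02,1.14,FALSE,60.0
high_red_processed_meat_intake,male,rural,Q4,0.2,1.12,1.03,1.21,FALSE,86.7
high_red_processed_meat_intake,male,rural,Q5,0.2,1.20,1.06,1.34,FALSE,136.7
high_red_processed_meat_intake,female,urban,Q1,0.2,1,1,1,TRUE,0
high_red_processed_meat_intake,female,urban,Q2,0.2,1.04,1.01,1.07,FALSE,33.3
high_red_processed_meat_intake,female,urban,Q3,0.2,1.09,1.03,1.15,FALSE,66.7
high_red_processed_meat_intake,female,urban,Q4,0.2,1.14,1.04,1.24,FALSE,100.0
high_red_processed_meat_intake,female,urban,Q5,0.2,1.22,1.06,1.38,FALSE,150.0
high_red_processed_meat_intake,female,rural,Q1,0.2,1,1,1,TRUE,0
high_red_processed_meat_intake,female,rural,Q2,0.2,1.04,1.01,1.07,FALSE,33.3
high_red_processed_meat_intake,female,rural,Q3,0.2,1.07,1.02,1.11,FALSE,50.0
high_red_processed_meat_intake,female,rural,Q4,0.2,1.12,1.03,1.20,FALSE,83.3
high_red_processed_meat_intake,female,rural,Q5,0.2,1.17,1.05,1.29,FALSE,116.7
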