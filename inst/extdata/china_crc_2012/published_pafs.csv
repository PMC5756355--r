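factor,sex,paf_pct
tobacco_smoking,male,8.4
tobacco_smoking,female,0.4
tobacco_smoking,total,4.9
alcohol_drinking,male,8.7
alcohol_drinking,female,1.1
alcohol_drinking,total,5.4
overweight_obesity,male,4.9
overweight_obesity,female,5.8
overweight_obesity,total,5.3
physical_inactivity,male,8.9
physical_inactivity,female,9.0
physical_inactivity,total,8.9
low_vegetable_intake,male,18.8
low_vegetable_intake,female,16.8
low_vegetable_intake,total,17.9
low_fruit_intake,male,6.2
low_fruit_intake,female,6.7
low_fruit_intake,total,6.4
high_red_processed_meat_intake,male,9.1
high_red_processed_meat_intake,female,7.9
high_red_processed_meat_intake,total,8.6
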