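category,sex,age_lo,age_hi,value,step,weight
early_adenoma_prev,male,35,35,0.12,I,0.05
early_adenoma_prev,female,35,35,0.084,I,0.05
early_adenoma_prev,male,40,40,0.16,I,0.05
early_adenoma_prev,female,40,40,0.112,I,0.05
early_adenoma_prev,male,45,45,0.2,I,0.05
early_adenoma_prev,female,45,45,0.14,I,0.05
early_adenoma_prev,male,50,50,0.25,I,0.05
early_adenoma_prev,female,50,50,0.175,I,0.05
early_adenoma_prev,male,55,55,0.29,I,0.05
early_adenoma_prev,female,55,55,0.203,I,0.05
early_adenoma_prev,male,60,60,0.33,I,0.05
early_adenoma_prev,female,60,60,0.231,I,0.05
early_adenoma_prev,male,65,65,0.36,I,0.05
early_adenoma_prev,female,65,65,0.252,I,0.05
early_adenoma_prev,male,70,70,0.38,I,0.05
early_adenoma_prev,female,70,70,0.266,I,0.05
early_adenoma_prev,male,75,75,0.4,I,0.05
early_adenoma_prev,female,75,75,0.28,I,0.05
early_adenoma_prev,male,80,80,0.41,I,0.05
early_adenoma_prev,female,80,80,0.287,I,0.05
adv_adenoma_prev,male,40,40,0.025,II,0.055556
adv_adenoma_prev,female,40,40,0.0163,II,0.055556
adv_adenoma_prev,male,45,45,0.034,II,0.055556
adv_adenoma_prev,female,45,45,0.0221,II,0.055556
adv_adenoma_prev,male,50,50,0.045,II,0.055556
adv_adenoma_prev,female,50,50,0.0292,II,0.055556
adv_adenoma_prev,male,55,55,0.055,II,0.055556
adv_adenoma_prev,female,55,55,0.0358,II,0.055556
adv_adenoma_prev,male,60,60,0.065,II,0.055556
adv_adenoma_prev,female,60,60,0.0423,II,0.055556
adv_adenoma_prev,male,65,65,0.075,II,0.055556
adv_adenoma_prev,female,65,65,0.0488,II,0.055556
adv_adenoma_prev,male,70,70,0.085,II,0.055556
adv_adenoma_prev,female,70,70,0.0553,II,0.055556
adv_adenoma_prev,male,75,75,0.093,II,0.055556
adv_adenoma_prev,female,75,75,0.0605,II,0.055556
adv_adenoma_prev,male,80,80,0.1,II,0.055556
adv_adenoma_prev,female,80,80,0.065,II,0.055556
crc_incidence,all,40,44,17,III,0.045455
crc_incidence,all,45,49,31,III,0.045455
crc_incidence,all,50,54,52,III,0.045455
crc_incidence,all,55,59,72,III,0.045455
crc_incidence,all,60,64,103,III,0.045455
crc_incidence,all,65,69,140,III,0.045455
crc_incidence,all,70,74,180,III,0.045455
crc_incidence,all,75,79,220,III,0.045455
crc_incidence,all,80,84,260,III,0.045455
crc_incidence,all,85,99,300,III,0.045455
crc_incidence,male,50,54,60,III,0.045455
crc_incidence,female,50,54,44,III,0.045455
crc_incidence,male,55,59,85,III,0.045455
crc_incidence,female,55,59,60,III,0.045455
crc_incidence,male,60,64,120,III,0.045455
crc_incidence,female,60,64,87,III,0.045455
crc_incidence,male,65,69,165,III,0.045455
crc_incidence,female,65,69,118,III,0.045455
crc_incidence,male,70,74,210,III,0.045455
crc_incidence,female,70,74,152,III,0.045455
crc_incidence,male,75,79,255,III,0.045455
crc_incidence,female,75,79,187,III,0.045455
crc_mortality,all,40,44,5,III,0.1
crc_mortality,all,45,49,9,III,0.1
crc_mortality,all,50,54,17,III,0.1
crc_mortality,all,55,59,26,III,0.1
crc_mortality,all,60,64,37,III,0.1
crc_mortality,all,65,69,52,III,0.1
crc_mortality,all,70,74,70,III,0.1
crc_mortality,all,75,79,95,III,0.1
crc_mortality,all,80,84,125,III,0.1
crc_mortality,all,85,99,180,III,0.1
rectum_incidence,all,40,49,6.5,III,0.25
colon_incidence,all,40,49,17,III,0.25
rectum_incidence,all,50,59,17,III,0.25
colon_incidence,all,50,59,45,III,0.25
rectum_incidence,all,60,69,33,III,0.25
colon_incidence,all,60,69,88,III,0.25
rectum_incidence,all,70,79,55,III,0.25
colon_incidence,all,70,79,145,III,0.25
multiplicity,all,50,50,0.4,I,0.333333
multiplicity,all,60,60,0.4,I,0.333333
multiplicity,all,70,70,0.4,I,0.333333
synchronous,all,0,99,0.035,III,1
stage_symptomatic,all,1,1,0.18,III,0.25
stage_symptomatic,all,2,2,0.3,III,0.25
stage_symptomatic,all,3,3,0.29,III,0.25
stage_symptomatic,all,4,4,0.23,III,0.25
stage_asymptomatic,all,1,1,0.44,III,0.25
stage_asymptomatic,all,2,2,0.31,III,0.25
stage_asymptomatic,all,3,3,0.18,III,0.25
stage_asymptomatic,all,4,4,0.07,III,0.25
trial_incidence_reduction,all,55,64,0.23,IV,1
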