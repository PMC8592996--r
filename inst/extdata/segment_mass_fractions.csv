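segment,base,female_specific
head,8.10,7.97
thorax,21.60,20.25
lumbar,13.90,12.43
pelvis,14.20,11.54
thighs,20.00,26.62
shanks,9.30,10.24
feet,2.90,2.60
upper_arms,5.60,4.70
lower_arms,3.20,2.60
hands,1.20,1.04
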