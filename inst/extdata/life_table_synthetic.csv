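age_from,age_to,sex,q
18,40,male,0.0012
40,45,male,0.002
45,50,male,0.003
50,55,male,0.0045
55,60,male,0.007
60,65,male,0.011
65,70,male,0.017
70,75,male,0.027
75,80,male,0.045
80,85,male,0.075
85,90,male,0.13
90,95,male,0.21
95,100,male,0.32
100,105,male,0.45
18,40,female,0.0006
40,45,female,0.001
45,50,female,0.0016
50,55,female,0.0025
55,60,female,0.004
60,65,female,0.006
65,70,female,0.010
70,75,female,0.016
75,80,female,0.028
80,85,female,0.050
85,90,female,0.095
90,95,female,0.165
95,100,female,0.27
100,105,female,0.40
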