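dataset,subject,accuracy
MHRC,1,64.29
MHRC,2,78.57
MHRC,3,85.71
MHRC,4,92.86
MHRC,5,71.43
MHRC,6,92.86
MHRC,7,96.88
MHRC,8,65.86
MHRC,9,91.45
MHRC,10,64.29
MHRC,11,64.29
MHRC,12,71.43
MHRC,13,78.57
MHRC,14,72.67
MHRC,15,92.86
MHRC,16,93.66
MHRC,17,75.57
MHRC,18,92.22
MHRC,19,78.57
MHRC,20,85.71
MHRC,21,92.86
MHRC,22,91.42
MHRC,23,64.29
MHRC,24,89.24
MHRC,25,92.86
MHRC,26,78.37
MHRC,27,66.15
MHRC,28,89.80
MHRC,29,92.87
MHRC,30,64.29
MHRC,31,92.85
MHRC,32,71.43
MHRC,33,71.43
MHRC,34,82.62
MHRC,35,71.43
MHRC,36,81.43
MHRC,37,90.15
MHRC,38,92.45
MHRC,39,94.85
RepOD,1,73.84
RepOD,2,78.34
RepOD,3,91.67
RepOD,4,98.34
RepOD,5,85.00
RepOD,6,80.00
RepOD,7,88.34
RepOD,8,83.35
RepOD,9,66.67
RepOD,10,81.67
RepOD,11,95.00
RepOD,12,70.00
RepOD,13,100.00
RepOD,14,83.34
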