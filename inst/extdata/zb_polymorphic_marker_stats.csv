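locus,na,pic,ho,he
ZBg01,3,0.48,0.13,0.57
ZBg02,3,0.58,0.40,0.68
ZBg03,4,0.59,0.64,0.68
ZBg04,5,0.69,0.36,0.77
ZBg07,5,0.58,0.40,0.64
ZBg11,3,0.47,0.11,0.57
ZBg17,2,0.27,0.40,0.34
ZBg18,5,0.66,0.00,0.73
ZBg19,2,0.33,0.47,0.43
ZBg21,3,0.30,0.38,0.34
ZBg24,5,0.73,0.54,0.80
ZBg30,4,0.60,0.86,0.68
ZBg31,2,0.36,0.00,0.49
ZBg34,2,0.37,0.00,0.51
ZBg35,3,0.40,0.33,0.46
ZBg36,2,0.16,0.20,0.19
ZBg40,4,0.50,0.40,0.61
ZBg45,3,0.47,0.56,0.57
ZBg46,3,0.44,0.00,0.51
ZBg71,5,0.45,0.33,0.49
ZBg73,3,0.59,0.23,0.69
ZBg74,3,0.49,0.07,0.60
ZBg76,3,0.47,0.00,0.57
ZBg77,4,0.57,0.00,0.64
ZBg83,4,0.46,0.23,0.53
ZBg84,5,0.67,0.00,0.74
ZBg86,2,0.27,0.27,0.33
ZBg89,3,0.35,0.33,0.40
ZBg90,2,0.34,0.09,0.45
ZBg91,5,0.47,0.43,0.52
ZBg92,7,0.75,0.73,0.81
ZBg94,3,0.40,0.15,0.48
ZBg95,3,0.55,0.67,0.65
ZBg96,5,0.60,0.00,0.68
ZBg97,3,0.42,0.07,0.48
ZBg98,3,0.35,0.20,0.40
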