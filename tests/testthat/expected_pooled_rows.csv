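snp,model,group,k,cases,controls,p,or,lo,hi,note
-1082A/G,allele,Overall,14,1593,2095,0.540,0.96,0.86,1.07,p_inconsistent
-1082A/G,allele,Asian,6,774,844,0.990,1.00,0.82,1.22,
-1082A/G,allele,Caucasian,7,751,1201,0.395,0.94,0.83,1.08,
-1082A/G,allele,Poland,3,402,468,0.562,0.95,0.78,1.14,
-1082A/G,allele,Y,9,1208,1305,0.326,0.93,0.82,1.07,
-1082A/G,allele,Asian/Y,3,543,455,0.751,1.06,0.74,1.51,
-1082A/G,allele,Caucasian/Y,5,597,800,0.238,0.91,0.78,1.06,
-1082A/G,allele,Poland/Y,3,402,468,0.562,0.95,0.78,1.14,
-1082A/G,homozygote,Overall,11,1288,1742,0.853,0.98,0.76,1.25,
-1082A/G,homozygote,Asian,3,469,491,0.144,1.55,0.86,2.78,
-1082A/G,homozygote,Caucasian,7,751,1201,0.390,0.88,0.66,1.17,
-1082A/G,homozygote,Poland,3,402,468,0.513,0.88,0.61,1.28,
-1082A/G,homozygote,Y,7,941,990,0.241,0.84,0.63,1.12,
-1082A/G,homozygote,Caucasian/Y,5,597,800,0.299,0.85,0.63,1.15,
-1082A/G,homozygote,Poland/Y,3,402,468,0.513,0.88,0.61,1.28,
-1082A/G,heterozygote,Overall,13,1499,1909,0.265,0.84,0.62,1.14,
-1082A/G,heterozygote,Asian,5,680,658,0.216,0.66,0.35,1.27,
-1082A/G,heterozygote,Caucasian,7,751,1201,0.720,0.93,0.65,1.35,
-1082A/G,heterozygote,Poland,3,402,468,0.753,1.05,0.77,1.43,
-1082A/G,heterozygote,Y,8,1114,1119,0.975,1.00,0.81,1.23,
-1082A/G,heterozygote,Caucasian/Y,5,597,800,0.683,0.94,0.71,1.26,
-1082A/G,heterozygote,Poland/Y,3,402,468,0.753,1.05,0.77,1.43,
-1082A/G,dominant,Overall,14,1536,2041,0.221,0.85,0.65,1.10,
-1082A/G,dominant,Asian,5,680,658,0.268,0.71,0.39,1.30,
-1082A/G,dominant,Caucasian,8,788,1333,0.502,0.90,0.66,1.23,
-1082A/G,dominant,Poland,3,402,468,0.957,0.99,0.75,1.32,
-1082A/G,dominant,Y,9,1151,1251,0.521,0.94,0.77,1.14,
-1082A/G,dominant,Caucasian/Y,6,634,932,0.369,0.88,0.68,1.16,
-1082A/G,dominant,Poland/Y,3,402,468,0.957,0.99,0.75,1.32,
-1082A/G,recessive,Overall,11,1288,1742,0.540,1.07,0.86,1.32,
-1082A/G,recessive,Asian,3,469,491,0.003,2.22,1.32,3.74,
-1082A/G,recessive,Caucasian,7,751,1201,0.538,0.93,0.72,1.18,
-1082A/G,recessive,Poland,3,402,468,0.358,0.86,0.62,1.19,
-1082A/G,recessive,Y,7,941,990,0.233,0.86,0.67,1.10,
-1082A/G,recessive,Caucasian/Y,5,597,800,0.295,0.87,0.67,1.13,
-1082A/G,recessive,Poland/Y,3,402,468,0.358,0.86,0.62,1.19,
-1082A/G,carrier,Overall,13,1499,1909,0.643,0.97,0.86,1.10,
-1082A/G,carrier,Asian,5,680,658,0.968,1.00,0.79,1.25,
-1082A/G,carrier,Caucasian,7,751,1201,0.608,0.96,0.82,1.12,
-1082A/G,carrier,Poland,3,402,468,0.751,0.96,0.77,1.21,
-1082A/G,carrier,Y,8,1114,1119,0.619,0.96,0.82,1.13,
-1082A/G,carrier,Caucasian/Y,5,597,800,0.475,0.94,0.78,1.12,
-1082A/G,carrier,Poland/Y,3,402,468,0.751,0.96,0.77,1.21,
-819T/C,allele,Overall,9,1228,1544,0.547,0.93,0.74,1.18,
-819T/C,allele,Asian,7,1074,1143,0.550,0.92,0.71,1.20,
-819T/C,allele,China,3,567,614,0.893,1.03,0.63,1.70,
-819T/C,allele,Y,7,1102,1404,0.610,0.94,0.73,1.21,y_membership
-819T/C,allele,Asian/Y,6,1036,1105,0.866,0.98,0.75,1.28,y_membership
-819T/C,homozygote,Overall,8,1134,1358,0.588,0.83,0.42,1.63,ci_print
-819T/C,homozygote,Asian,6,980,957,0.915,0.96,0.46,1.99,
-819T/C,homozygote,Y,6,1008,1218,0.870,1.06,0.54,2.07,y_membership
-819T/C,homozygote,Asian/Y,5,942,919,0.593,1.19,0.63,2.26,y_membership
-819T/C,heterozygote,Overall,8,1134,1358,0.405,0.83,0.55,1.28,
-819T/C,heterozygote,Asian,6,980,957,0.697,0.90,0.54,1.51,
-819T/C,heterozygote,Y,6,1008,1218,0.892,0.97,0.65,1.45,y_membership
-819T/C,heterozygote,Asian/Y,5,942,919,0.995,1.00,0.62,1.62,y_membership
-819T/C,dominant,Overall,8,1134,1358,0.433,0.84,0.55,1.30,
-819T/C,dominant,Asian,6,980,957,0.693,0.90,0.53,1.52,
-819T/C,dominant,Y,6,1008,1218,0.845,0.96,0.63,1.47,y_membership
-819T/C,dominant,Asian/Y,5,942,919,0.975,1.01,0.61,1.66,y_membership
-819T/C,recessive,Overall,8,1134,1358,0.821,1.05,0.69,1.60,
-819T/C,recessive,Asian,6,980,957,0.991,1.00,0.64,1.55,
-819T/C,recessive,Y,6,1008,1218,0.900,1.03,0.65,1.64,y_membership
-819T/C,recessive,Asian/Y,5,942,919,0.706,1.09,0.70,1.70,y_membership
-819T/C,carrier,Overall,8,1134,1358,0.801,1.02,0.88,1.17,
-819T/C,carrier,Asian,6,980,957,0.816,1.02,0.87,1.19,
-819T/C,carrier,Y,6,1008,1218,0.867,1.01,0.87,1.18,y_membership
-819T/C,carrier,Asian/Y,5,942,919,0.631,1.04,0.89,1.22,y_membership
-592A/C,allele,Overall,9,1032,1363,0.109,0.85,0.70,1.04,
-592A/C,allele,Asian,6,774,844,0.033,0.85,0.73,0.99,
-592A/C,allele,Caucasian,3,258,519,0.788,0.92,0.49,1.73,
-592A/C,allele,Y,8,994,1325,0.204,0.88,0.73,1.07,
-592A/C,allele,Asian/Y,5,736,806,0.086,0.87,0.74,1.02,
-592A/C,allele,Caucasian/Y,3,258,519,0.788,0.92,0.49,1.73,
-592A/C,homozygote,Overall,8,938,1177,0.227,0.72,0.42,1.23,
-592A/C,homozygote,Asian,5,680,658,0.353,0.75,0.40,1.38,
-592A/C,homozygote,Caucasian,3,258,519,0.582,0.71,0.21,2.38,ci_print
-592A/C,homozygote,Y,7,900,1139,0.349,0.80,0.50,1.28,
-592A/C,homozygote,Asian/Y,4,642,620,0.471,0.86,0.56,1.30,
-592A/C,homozygote,Caucasian/Y,3,258,519,0.582,0.71,0.21,2.38,ci_print
-592A/C,heterozygote,Overall,8,938,1177,0.039,0.77,0.59,0.99,
-592A/C,heterozygote,Asian,5,680,658,0.061,0.77,0.58,1.01,
-592A/C,heterozygote,Caucasian,3,258,519,0.387,0.76,0.41,1.41,
-592A/C,heterozygote,Y,7,900,1139,0.093,0.80,0.62,1.04,
-592A/C,heterozygote,Asian/Y,4,642,620,0.146,0.81,0.61,1.08,
-592A/C,heterozygote,Caucasian/Y,3,258,519,0.387,0.76,0.41,1.41,
-592A/C,dominant,Overall,8,938,1177,0.026,0.76,0.60,0.97,
-592A/C,dominant,Asian,5,680,658,0.049,0.77,0.59,1.00,
-592A/C,dominant,Caucasian,3,258,519,0.290,0.73,0.41,1.31,
-592A/C,dominant,Y,7,900,1139,0.069,0.80,0.62,1.02,
-592A/C,dominant,Asian/Y,4,642,620,0.128,0.81,0.62,1.06,
-592A/C,dominant,Caucasian/Y,3,258,519,0.290,0.73,0.41,1.31,
-592A/C,recessive,Overall,8,938,1177,0.416,0.86,0.61,1.23,
-592A/C,recessive,Asian,5,680,658,0.194,0.83,0.62,1.10,
-592A/C,recessive,Caucasian,3,258,519,0.892,0.94,0.41,2.19,
-592A/C,recessive,Y,7,900,1139,0.597,0.91,0.63,1.30,
-592A/C,recessive,Asian/Y,4,642,620,0.324,0.86,0.64,1.16,
-592A/C,recessive,Caucasian/Y,3,258,519,0.892,0.94,0.41,2.19,
-592A/C,carrier,Overall,8,938,1177,0.170,0.90,0.77,1.05,
-592A/C,carrier,Asian,5,680,658,0.180,0.88,0.73,1.06,
-592A/C,carrier,Caucasian,3,258,519,0.640,0.94,0.71,1.24,
-592A/C,carrier,Y,7,900,1139,0.244,0.91,0.77,1.07,
-592A/C,carrier,Asian/Y,4,642,620,0.273,0.90,0.74,1.09,
-592A/C,carrier,Caucasian/Y,3,258,519,0.640,0.94,0.71,1.24,
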