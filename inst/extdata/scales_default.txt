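# Default amino-acid property scales shipped with morfmlp.
#
# 15 scales = 13 physicochemical scales in the AAindex tradition plus
# two structure/disorder propensity scales.  Together with the
# topological-entropy functional (computed in code, not tabulated here)
# these give the 16 per-window sequence properties.
#
# Provenance: values transcribed by the package authors from the primary
# literature cited on each name line.  The two propensity scales are
# documented substitutes for loop/disorder propensities: TOP-IDP
# (Campen et al. 2008) stands in for a missing-density (REMARK 465 type)
# disorder propensity, and the Chou-Fasman turn scale for a
# coil-vs-regular-structure propensity.  Any scale can be replaced at
# run time via --scales; blocks are ">NAME description" + 20
# "letter value" lines.
#
>KD_HYDROPATHY Kyte-Doolittle hydropathy (AAindex KYTJ820101)
A 1.8
R -4.5
N -3.5
D -3.5
C 2.5
Q -3.5
E -3.5
G -0.4
H -3.2
I 4.5
L 3.8
K -3.9
M 1.9
F 2.8
P -1.6
S -0.8
T -0.7
W -0.9
Y -1.3
V 4.2
>HW_HYDROPHILICITY Hopp-Woods hydrophilicity (AAindex HOPT810101)
A -0.5
R 3.0
N 0.2
D 3.0
C -1.0
Q 0.2
E 3.0
G 0.0
H -0.5
I -1.8
L -1.8
K 3.0
M -1.3
F -2.5
P 0.0
S 0.3
T -0.4
W -3.4
Y -2.3
V -1.5
>EISENBERG_HPHOB Eisenberg consensus hydrophobicity (AAindex EISD840101)
A 0.62
R -2.53
N -0.78
D -0.90
C 0.29
Q -0.85
E -0.74
G 0.48
H -0.40
I 1.38
L 1.06
K -1.50
M 0.64
F 1.19
P 0.12
S -0.18
T -0.05
W 0.81
Y 0.26
V 1.08
>GRANTHAM_POLARITY Grantham polarity (AAindex GRAR740102)
A 8.1
R 10.5
N 11.6
D 13.0
C 5.5
Q 10.5
E 12.3
G 9.0
H 10.4
I 5.2
L 4.9
K 11.3
M 5.7
F 5.2
P 8.0
S 9.2
T 8.6
W 5.4
Y 6.2
V 5.9
>ZIMMERMAN_PI Zimmerman isoelectric point (AAindex ZIMJ680104)
A 6.00
R 10.76
N 5.41
D 2.77
C 5.05
Q 5.65
E 3.22
G 5.97
H 7.59
I 6.02
L 5.98
K 9.74
M 5.74
F 5.48
P 6.30
S 5.68
T 5.66
W 5.89
Y 5.66
V 5.96
>ZIMMERMAN_POLARITY Zimmerman polarity (AAindex ZIMJ680103)
A 0.00
R 52.00
N 3.38
D 49.70
C 1.48
Q 3.53
E 49.90
G 0.00
H 51.60
I 0.13
L 0.13
K 49.50
M 1.43
F 0.35
P 1.58
S 1.67
T 1.66
W 2.10
Y 1.61
V 0.13
>ZIMMERMAN_BULKINESS Zimmerman bulkiness (AAindex ZIMJ680102)
A 11.50
R 14.28
N 12.82
D 11.68
C 13.46
Q 14.45
E 13.57
G 3.40
H 13.69
I 21.40
L 21.40
K 15.71
M 16.25
F 19.80
P 17.43
S 9.47
T 15.77
W 21.67
Y 18.03
V 21.57
>KLEIN_NET_CHARGE Klein net charge (AAindex KLEP840101)
A 0
R 1
N 0
D -1
C 0
Q 0
E -1
G 0
H 0
I 0
L 0
K 1
M 0
F 0
P 0
S 0
T 0
W 0
Y 0
V 0
>CF_HELIX Chou-Fasman alpha-helix propensity (AAindex CHOP780201)
A 1.42
R 0.98
N 0.67
D 1.01
C 0.70
Q 1.11
E 1.51
G 0.57
H 1.00
I 1.08
L 1.21
K 1.16
M 1.45
F 1.13
P 0.57
S 0.77
T 0.83
W 1.08
Y 0.69
V 1.06
>CF_SHEET Chou-Fasman beta-sheet propensity (AAindex CHOP780202)
A 0.83
R 0.93
N 0.89
D 0.54
C 1.19
Q 1.10
E 0.37
G 0.75
H 0.87
I 1.60
L 1.30
K 0.74
M 1.05
F 1.38
P 0.55
S 0.75
T 1.19
W 1.37
Y 1.47
V 1.70
>BP_FLEXIBILITY Bhaskaran-Ponnuswamy average flexibility (AAindex BHAR880101)
A 0.357
R 0.529
N 0.463
D 0.511
C 0.346
Q 0.493
E 0.497
G 0.544
H 0.323
I 0.462
L 0.365
K 0.466
M 0.295
F 0.314
P 0.509
S 0.507
T 0.444
W 0.305
Y 0.420
V 0.386
>ZAMYATNIN_VOLUME Zamyatnin residue volume (AAindex GOLD730102 family)
A 88.6
R 173.4
N 114.1
D 111.1
C 108.5
Q 143.8
E 138.4
G 60.1
H 153.2
I 166.7
L 166.7
K 168.6
M 162.9
F 189.9
P 112.7
S 89.0
T 116.1
W 227.8
Y 193.6
V 140.0
>RESIDUE_MW Amino-acid residue molecular weight (AAindex FASG760101)
A 89.09
R 174.20
N 132.12
D 133.10
C 121.15
Q 146.15
E 147.13
G 75.07
H 155.16
I 131.17
L 131.17
K 146.19
M 149.21
F 165.19
P 115.13
S 105.09
T 119.12
W 204.23
Y 181.19
V 117.15
>TOPIDP_DISORDER TOP-IDP intrinsic disorder propensity (Campen et al. 2008; substitute for a REMARK-465 missing-density propensity)
A 0.060
R 0.180
N 0.007
D 0.192
C 0.020
Q 0.318
E 0.736
G 0.166
H 0.303
I -0.486
L -0.326
K 0.586
M -0.397
F -0.697
P 0.987
S 0.341
T 0.059
W -0.884
Y -0.510
V -0.121
>CF_TURN Chou-Fasman beta-turn propensity (AAindex CHOP780203; substitute for a coil-vs-structure propensity)
A 0.66
R 0.95
N 1.56
D 1.46
C 1.19
Q 0.98
E 0.74
G 1.56
H 0.95
I 0.47
L 0.59
K 1.01
M 0.60
F 0.60
P 1.52
S 1.43
T 0.96
W 0.96
Y 1.14
V 0.50
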