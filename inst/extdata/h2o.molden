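[Molden Format]
made by pyscf v[2.12.1]
[Atoms] (AU)
O   1   8     0.00000000000000     0.00000000000000     0.31711674243918
H   2   1     0.00000000000000     1.43992039429527    -0.77889928344309
H   3   1     0.00000000000000    -1.43992039429527    -0.77889928344309
[GTO]
1 0
 s    6 1.00
          27032.382631  0.00057227335211155
          4052.3871392  0.0044353233492995
           922.3272271   0.023020107706038
          261.24070989   0.092822490667928
          85.354641351    0.29378500009671
          31.035035245    0.67401604501641
 s    2 1.00
          12.260860728    0.63839937025506
          4.9987076005    0.39534587125718
 s    1 1.00
          1.1703108158                   1
 s    1 1.00
         0.46474740994                   1
 s    1 1.00
         0.18504536357                   1
 p    4 1.00
          63.274954801   0.012018332222616
          14.627049379   0.083005421790056
          4.4501223456    0.31991743925964
          1.5275799647    0.70715542916104
 p    1 1.00
         0.52935117943                   1
 p    1 1.00
          0.1747842127                   1
 d    1 1.00
                 2.314                   1
 d    1 1.00
                 0.645                   1
 f    1 1.00
                 1.428                   1

2 0
 s    3 1.00
             34.061341   0.025439307208879
             5.1235746    0.19008594890375
             1.1646626    0.85244113011042
 s    1 1.00
            0.32723041                   1
 s    1 1.00
            0.10307241                   1
 p    1 1.00
                   0.8                   1

3 0
 s    3 1.00
             34.061341   0.025439307208879
             5.1235746    0.19008594890375
             1.1646626    0.85244113011042
 s    1 1.00
            0.32723041                   1
 s    1 1.00
            0.10307241                   1
 p    1 1.00
                   0.8                   1

[5d]
[7f]
[9g]

[MO]
 Sym= A
 Ene=    -19.24625092
 Spin= Alpha
 Occup=    2.00000
1 4.35326048e-01
2 6.39785716e-01
3 3.31226175e-02
4 -2.09762727e-02
5 8.59435666e-03
6 -3.28515868e-18
7 1.30748760e-16
8 -1.80921183e-03
9 1.74549942e-18
10 -1.25583892e-15
11 2.82829793e-03
12 -7.35191804e-19
13 4.80147905e-17
14 -1.06190517e-03
15 3.23491013e-05
16 -3.41858380e-19
17 -5.87931589e-17
18 -2.12088414e-04
19 -5.91688214e-19
20 -1.26241848e-04
21 1.31455997e-19
22 6.58413074e-16
23 9.00495018e-04
24 4.52285079e-19
25 -1.42830031e-04
26 1.75849614e-19
27 -6.26096854e-17
28 -3.19972241e-04
29 1.02360470e-19
30 4.69513213e-20
31 6.94357667e-17
32 8.12386569e-04
33 1.49842951e-03
34 -1.78328466e-03
35 -1.77441081e-19
36 -8.24187890e-04
37 5.70342379e-04
38 8.12386569e-04
39 1.49842951e-03
40 -1.78328466e-03
41 4.78078586e-20
42 8.24187890e-04
43 5.70342379e-04
 Sym= A
 Ene=    -1.112962664
 Spin= Alpha
 Occup=    2.00000
1 -9.72649742e-02
2 -2.29207437e-01
3 3.31378841e-01
4 4.40403611e-01
5 1.59695537e-01
6 1.79251741e-16
7 -1.32113602e-15
8 -8.32571299e-02
9 -1.09299268e-17
10 8.73414581e-15
11 -7.31151657e-02
12 -3.57961842e-17
13 2.03613285e-15
14 -1.14142939e-02
15 1.17707906e-03
16 -8.77313841e-18
17 4.03580702e-16
18 -4.21796451e-03
19 5.13505959e-18
20 4.67149352e-03
21 -6.30084128e-18
22 -5.37130342e-15
23 -1.14428913e-02
24 -4.51584022e-19
25 1.58672572e-03
26 3.90885624e-18
27 4.57579664e-16
28 4.68823912e-03
29 2.39186909e-19
30 5.51711261e-20
31 -4.05740240e-16
32 9.37186584e-02
33 6.90519110e-02
34 6.23910414e-03
35 8.27114244e-18
36 -1.42611362e-02
37 7.78622942e-03
38 9.37186584e-02
39 6.90519110e-02
40 6.23910414e-03
41 9.67181953e-18
42 1.42611362e-02
43 7.78622942e-03
 Sym= A
 Ene=   -0.6217977961
 Spin= Alpha
 Occup=    2.00000
1 3.62856894e-17
2 -5.37437560e-17
3 -8.23088638e-16
4 2.56432530e-15
5 -5.57789555e-15
6 7.46595220e-16
7 3.82837326e-01
8 -1.76063604e-16
9 6.25383267e-16
10 3.04035403e-01
11 -7.39431835e-16
12 1.10352903e-15
13 1.20820915e-01
14 1.62964512e-15
15 -4.12881608e-17
16 2.21553987e-16
17 -1.18685186e-02
18 -3.31199320e-18
19 -3.63821316e-16
20 1.54053231e-16
21 -5.50511908e-16
22 -2.71359798e-02
23 2.88129381e-16
24 1.98665524e-16
25 -2.22150935e-16
26 -1.93219228e-16
27 1.08454820e-03
28 -3.50605174e-16
29 -1.52302833e-16
30 -1.45168945e-17
31 -5.19417049e-03
32 1.47639780e-01
33 1.86181725e-01
34 5.45446119e-02
35 3.13091198e-16
36 -7.70643946e-03
37 1.67610517e-02
38 -1.47639780e-01
39 -1.86181725e-01
40 -5.45446119e-02
41 1.84724829e-16
42 -7.70643946e-03
43 -1.67610517e-02
 Sym= A
 Ene=   -0.4749858272
 Spin= Alpha
 Occup=    2.00000
1 -3.62984260e-02
2 -8.71497140e-02
3 1.36353325e-01
4 1.95114544e-01
5 2.15960176e-01
6 4.34151554e-16
7 -8.23310029e-16
8 4.15614523e-01
9 9.09848966e-16
10 4.93801548e-15
11 3.30532410e-01
12 8.47651922e-16
13 -6.31562059e-15
14 2.34253962e-01
15 -4.65604182e-03
16 -2.22547608e-18
17 -4.18092785e-16
18 2.47731574e-03
19 -4.48017790e-19
20 -2.66016006e-02
21 -5.82175570e-17
22 -1.36553944e-15
23 -4.88836348e-05
24 -7.54505265e-18
25 8.64931144e-04
26 5.55929297e-18
27 4.37436734e-17
28 -3.89454016e-03
29 -3.71315753e-18
30 -8.64182863e-18
31 -4.75451447e-16
32 -8.58943797e-02
33 -1.22177419e-01
34 -3.67992026e-02
35 4.33557371e-17
36 1.63662416e-02
37 1.08394139e-02
38 -8.58943797e-02
39 -1.22177419e-01
40 -3.67992026e-02
41 2.09135767e-17
42 -1.63662416e-02
43 1.08394139e-02
 Sym= A
 Ene=   -0.4005337408
 Spin= Alpha
 Occup=    2.00000
1 5.92815397e-17
2 9.42785051e-17
3 8.27288637e-16
4 -3.27910939e-15
5 1.66976850e-15
6 4.73385911e-01
7 -1.28078289e-15
8 -6.85174783e-16
9 3.91480328e-01
10 1.17679123e-15
11 2.47354316e-16
12 3.31275456e-01
13 2.34043772e-16
14 -8.69396216e-16
15 1.34153494e-16
16 -4.39561276e-03
17 1.82006545e-16
18 -3.43986829e-16
19 -4.85743604e-17
20 -2.28635348e-16
21 -2.68027737e-02
22 -1.33802845e-15
23 8.29208334e-16
24 -8.35768998e-17
25 -3.16099295e-17
26 2.05108032e-03
27 9.11248588e-17
28 -2.03245582e-17
29 -1.56125515e-16
30 -5.16676999e-03
31 8.89542056e-17
32 -7.91956891e-17
33 -8.88127391e-16
34 -1.30140933e-15
35 2.60796234e-02
36 6.46213429e-16
37 -7.46787589e-16
38 1.39239049e-15
39 2.58101816e-15
40 -5.87650247e-16
41 2.60796234e-02
42 1.29222548e-15
43 1.25174005e-15
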