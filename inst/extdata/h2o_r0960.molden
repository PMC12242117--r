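[Molden Format]
made by pyscf v[2.12.1]
[Atoms] (AU)
O   1   8     0.00000000000000     0.00000000000000     0.31711674243918
H   2   1     0.00000000000000     1.44353727892145    -0.78165232696533
H   3   1     0.00000000000000    -1.44353727892145    -0.78165232696533
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
 Ene=    -19.24666053
 Spin= Alpha
 Occup=    2.00000
1 4.35327805e-01
2 6.39786979e-01
3 3.31196658e-02
4 -2.09732959e-02
5 8.57073982e-03
6 1.14092522e-17
7 1.96306335e-17
8 -1.80912513e-03
9 -6.45634252e-18
10 -1.23957916e-16
11 2.83580886e-03
12 3.21700322e-18
13 -4.16134650e-17
14 -1.05828863e-03
15 3.23624258e-05
16 -4.29451337e-19
17 -9.55255988e-18
18 -2.11877038e-04
19 -9.25801799e-19
20 -1.26582395e-04
21 1.42291535e-18
22 8.64310984e-17
23 9.06465896e-04
24 5.34724321e-19
25 -1.44046617e-04
26 -2.83297793e-19
27 -1.74954122e-17
28 -3.22432205e-04
29 -5.99150687e-20
30 -1.01128557e-19
31 6.68784358e-18
32 8.10347954e-04
33 1.50635071e-03
34 -1.77842358e-03
35 4.10189650e-19
36 -8.33446093e-04
37 5.77577424e-04
38 8.10347954e-04
39 1.50635071e-03
40 -1.77842358e-03
41 6.93236948e-19
42 8.33446093e-04
43 5.77577424e-04
 Sym= A
 Ene=     -1.11190847
 Spin= Alpha
 Occup=    2.00000
1 -9.72947443e-02
2 -2.29277332e-01
3 3.31475486e-01
4 4.40989459e-01
5 1.60173382e-01
6 2.96373755e-16
7 -2.01771791e-15
8 -8.28754982e-02
9 -9.33342182e-17
10 1.37333311e-14
11 -7.30238871e-02
12 1.91681628e-16
13 -1.40497009e-15
14 -1.14211520e-02
15 1.16663555e-03
16 -4.93807010e-17
17 3.66260013e-16
18 -4.18478740e-03
19 -5.23585285e-18
20 4.66516722e-03
21 -6.06267373e-17
22 -6.33202516e-15
23 -1.14786889e-02
24 -3.27660613e-17
25 1.58049683e-03
26 1.55830871e-17
27 4.49855090e-16
28 4.66758904e-03
29 -4.76703691e-18
30 -4.80959878e-18
31 -5.13681765e-16
32 9.33255723e-02
33 6.89627062e-02
34 6.26554172e-03
35 -2.65775728e-17
36 -1.41921198e-02
37 7.75725765e-03
38 9.33255723e-02
39 6.89627062e-02
40 6.26554172e-03
41 -2.76882221e-17
42 1.41921198e-02
43 7.75725765e-03
 Sym= A
 Ene=   -0.6208419665
 Spin= Alpha
 Occup=    2.00000
1 3.70819204e-16
2 6.83378973e-16
3 1.86710425e-15
4 -1.07732241e-14
5 7.15548058e-15
6 -6.31069651e-16
7 3.82544899e-01
8 -9.50505454e-15
9 -8.57807093e-16
10 3.04268470e-01
11 -3.71540064e-15
12 -2.49116865e-16
13 1.21149455e-01
14 -8.13512255e-15
15 5.43894002e-16
16 -2.15180237e-16
17 -1.18030386e-02
18 -3.53904962e-16
19 -2.08371514e-16
20 3.15095585e-17
21 1.18835881e-16
22 -2.72367825e-02
23 7.32709592e-16
24 3.66915973e-19
25 1.12059767e-16
26 -3.96782615e-19
27 1.09006597e-03
28 2.01030813e-16
29 -8.34624599e-17
30 1.14446718e-16
31 -5.18684236e-03
32 1.47346515e-01
33 1.86252918e-01
34 5.48158770e-02
35 -1.40953691e-17
36 -7.64193903e-03
37 1.66911147e-02
38 -1.47346515e-01
39 -1.86252918e-01
40 -5.48158770e-02
41 6.11991644e-17
42 -7.64193903e-03
43 -1.66911147e-02
 Sym= A
 Ene=   -0.4747669019
 Spin= Alpha
 Occup=    2.00000
1 -3.62671117e-02
2 -8.70784689e-02
3 1.36357139e-01
4 1.94607866e-01
5 2.15772946e-01
6 -1.59399950e-15
7 6.08818236e-15
8 4.15436627e-01
9 -1.15453135e-15
10 1.46589529e-14
11 3.30508498e-01
12 -1.42842385e-15
13 6.28499634e-16
14 2.34301266e-01
15 -4.63025837e-03
16 1.74867776e-16
17 -1.12625364e-15
18 2.47372177e-03
19 2.15164114e-17
20 -2.65717455e-02
21 6.69250548e-17
22 -5.00004488e-15
23 -1.45084549e-05
24 -4.18714070e-17
25 8.59457036e-04
26 9.06085872e-18
27 3.87102430e-16
28 -3.89437636e-03
29 -1.78242029e-17
30 -6.23928821e-17
31 -1.78180265e-15
32 -8.59484839e-02
33 -1.22481999e-01
34 -3.71728216e-02
35 -1.23462420e-16
36 1.63319652e-02
37 1.08024326e-02
38 -8.59484839e-02
39 -1.22481999e-01
40 -3.71728216e-02
41 -1.53116872e-16
42 -1.63319652e-02
43 1.08024326e-02
 Sym= A
 Ene=   -0.4003302599
 Spin= Alpha
 Occup=    2.00000
1 1.27997608e-16
2 1.79811288e-16
3 8.33469002e-16
4 -3.70878824e-15
5 -3.82735066e-15
6 4.73441723e-01
7 8.08987798e-16
8 2.87237130e-15
9 3.91457997e-01
10 9.84986647e-16
11 2.52779830e-15
12 3.31408630e-01
13 6.96195300e-16
14 2.67640135e-15
15 9.08555672e-18
16 -4.37469253e-03
17 -2.11677973e-16
18 2.61875297e-16
19 -1.49474601e-16
20 -5.65977828e-17
21 -2.67725967e-02
22 -4.11846288e-17
23 3.52542054e-16
24 6.09487077e-16
25 -3.38397294e-17
26 2.04740814e-03
27 1.77446288e-16
28 -8.32073990e-18
29 -4.60124694e-16
30 -5.15639412e-03
31 -4.11666611e-17
32 2.29651312e-16
33 4.67214495e-17
34 6.42011831e-15
35 2.60197309e-02
36 1.70519218e-16
37 2.01722607e-17
38 2.07069257e-16
39 9.78664279e-16
40 5.08036813e-15
41 2.60197309e-02
42 1.13674812e-16
  43                    -0
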