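station,item,D_i,P_i
1,1,0.43,-0.05
1,2,0.75,0.34
1,3,0.84,0.48
1,4,0.97,0.07
1,5,0.18,-0.07
1,6,0.18,-0.07
1,7,0.33,-0.06
1,8,0.34,-0.03
1,9,0.28,0.1
1,10,0.3,-0.16
2,1,0.67,0.16
2,2,0.34,0.1
2,3,0.7,0.1
2,4,0.28,-0.41
2,5,0.8,0.28
2,6,0.69,0.21
2,7,0.66,0.41
2,8,0.03,-0.12
2,9,0.08,0.01
2,10,0.07,0.19
3,1,0.39,0.24
3,2,0.2,0.06
3,3,0.57,-0.03
3,4,0.48,-0.09
3,5,0.57,0.25
3,6,0.67,0.24
3,7,0.84,0.34
3,8,0.87,0.29
3,9,0.98,0.6
3,10,0.9,0.35
4,1,0.89,0.07
4,2,0.39,0.25
4,3,0.95,0.12
4,4,0.56,0.55
4,5,0.7,0.17
4,6,0.93,-0.03
4,7,0.41,0.09
4,8,0.52,0.62
4,9,0.92,0.41
4,10,0.61,0.31
5,1,0.92,0.23
5,2,0.88,0.27
5,3,0.89,0.24
5,4,0.97,0.3
5,5,0.97,0.3
5,6,0.93,0.16
5,7,0.86,0.07
5,8,0.65,0.29
5,9,0.86,0.36
5,10,0.67,0.15
6,1,0.82,0.11
6,2,0.96,0.16
6,3,0.86,0.12
6,4,0.72,0.14
6,5,0.75,0.06
6,6,0.71,0.17
6,7,0.91,0.1
6,8,0.83,0.19
6,9,0.8,0.1
6,10,0.57,0.17
7,1,0.77,0.1
7,2,0.72,0.11
7,3,0.75,0.44
7,4,0.97,0.14
7,5,0.93,0.15
7,6,0.72,0.29
7,7,0.92,0.28
7,8,0.68,0.18
7,9,0.98,0.25
7,10,0.78,0.33
8,1,0.67,-0.35
8,2,0.08,-0.26
8,3,0.24,-0.49
8,4,0.01,-0.2
8,5,0.92,0.41
8,6,0.86,0.22
8,7,0.99,-0.06
8,8,0.92,0.34
8,9,0.92,0.14
8,10,0.95,0.17
9,1,0.67,0.31
9,2,0.65,-0.06
9,3,0.91,0.08
9,4,0.45,0.1
9,5,0.84,0.28
9,6,0.53,0.43
9,7,0.14,0.26
9,8,0.22,0.24
9,9,0.77,0.23
9,10,0.69,0.19
10,1,0.82,0.09
10,2,0.34,-0.01
10,3,0.89,0.1
10,4,0.62,0.09
10,5,0.13,0.04
10,6,0.81,0.33
10,7,0.81,0.17
10,8,0.62,0.06
10,9,0.62,0.05
10,10,0.6,0.1
11,1,0.59,0.11
11,2,0.11,0.3
11,3,0.63,0.28
11,4,0.21,0.24
11,5,0.78,0.11
11,6,0.31,0.36
11,7,0.64,0.29
11,8,0.11,0.22
11,9,0.06,0.07
11,10,0.1,0.07
12,1,0.95,0.14
12,2,0.76,0.13
12,3,0.43,0.08
12,4,0.73,0.23
12,5,0.94,0.23
12,6,0.82,0.22
12,7,0.86,0.19
12,8,0.95,0.38
12,9,0.76,0.02
12,10,0.05,-0.19
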