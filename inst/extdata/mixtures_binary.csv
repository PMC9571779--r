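mixture_no,component_a,component_b,ratio_text,pEC50mix_exp,pEC50mix_pred_mlr,resid_mlr,pEC50mix_pred_rbfnn,resid_rbfnn,split,cv_block
1,1,14,1\1,2.44,2.10,0.34,2.75,-0.31,test,A
2,2,14,1\1,2.63,2.10,0.53,2.71,-0.08,train,B
3,3,14,1\1,2.77,2.10,0.67,2.72,0.05,train,C
4,4,14,1\1,2.78,2.09,0.69,2.72,0.06,train,D
5,5,14,1\1,2.80,3.10,-0.30,2.90,-0.10,train,E
6,6,14,1\1,2.84,2.56,0.28,2.76,0.08,test,A
7,7,14,1\1,2.84,2.92,-0.08,2.86,-0.02,train,B
8,8,14,1\1,2.83,3.26,-0.43,2.71,0.12,train,C
9,9,14,1\1,2.84,3.22,-0.38,2.70,0.14,train,D
10,10,14,1\1,2.85,3.34,-0.49,2.87,-0.02,test,E
11,11,14,1\1,2.83,3.03,-0.20,2.99,-0.16,train,A
12,12,14,1\1,2.84,3.15,-0.31,3.00,-0.16,test,B
13,13,14,1\1,2.85,3.53,-0.68,2.86,-0.01,train,C
14,5,15,1\1,3.15,3.16,-0.01,3.22,-0.07,train,D
15,6,15,1\1,3.26,2.62,0.64,3.40,-0.14,train,E
16,7,15,1\1,3.25,2.97,0.28,3.34,-0.09,train,A
17,8,15,1\1,3.24,3.31,-0.07,3.28,-0.04,train,B
18,9,15,1\1,3.26,3.28,-0.02,3.29,-0.03,train,C
19,10,15,1\1,3.27,3.39,-0.12,3.01,0.26,train,D
20,11,15,1\1,3.22,3.09,0.13,2.64,0.58,train,E
21,13,15,1\1,3.28,3.58,-0.30,2.58,0.70,test,A
22,1,16,1\1,2.64,2.82,-0.18,3.34,-0.70,test,B
23,2,16,1\1,2.97,2.82,0.15,3.23,-0.26,train,C
24,3,16,1\1,3.39,2.82,0.57,3.22,0.17,train,D
25,5,16,1\1,3.51,3.82,-0.31,3.84,-0.33,test,E
26,6,16,1\1,3.83,3.28,0.55,3.84,-0.01,train,A
27,7,16,1\1,3.78,3.64,0.14,3.83,-0.05,train,B
28,8,16,1\1,3.75,3.98,-0.23,3.86,-0.11,train,C
29,9,16,1\1,3.83,3.94,-0.11,3.83,0.00,train,D
30,10,16,1\1,3.86,4.06,-0.20,3.91,-0.05,test,E
31,11,16,1\1,3.70,3.75,-0.05,3.73,-0.03,train,A
32,12,16,1\1,3.77,3.87,-0.10,3.61,0.16,train,B
33,13,16,1\1,3.90,4.25,-0.35,4.45,-0.55,test,C
34,1,17,1\1,2.18,2.08,0.10,2.16,0.02,train,D
35,3,17,1\1,2.33,2.09,0.24,2.05,0.28,train,E
36,4,17,1\1,2.34,2.08,0.26,2.06,0.28,test,A
37,5,17,1\1,2.34,3.09,-0.75,2.70,-0.36,train,B
38,6,17,1\1,2.36,2.55,-0.19,2.48,-0.12,train,C
39,7,17,1\1,2.36,2.90,-0.54,2.67,-0.31,train,D
40,8,17,1\1,2.36,3.25,-0.89,2.95,-0.59,test,E
41,10,17,1\1,2.36,3.32,-0.96,2.82,-0.46,train,A
42,11,17,1\1,2.35,3.02,-0.67,2.32,0.03,train,B
43,12,17,1\1,2.35,3.14,-0.79,2.37,-0.02,train,C
44,13,17,1\1,2.36,3.51,-1.15,2.45,-0.09,train,D
45,5,18,1\1,3.45,3.87,-0.42,3.70,-0.25,train,E
46,6,18,1\1,3.72,3.33,0.39,3.83,-0.11,test,A
47,7,18,1\1,3.68,3.68,0.00,3.82,-0.14,train,B
48,8,18,1\1,3.66,4.03,-0.37,3.88,-0.22,train,C
49,10,18,1\1,3.74,4.10,-0.36,3.66,0.08,test,D
50,11,18,1\1,3.62,3.80,-0.18,3.15,0.47,train,E
51,12,18,1\1,3.67,3.92,-0.25,3.51,0.16,train,A
52,13,18,1\1,3.78,4.29,-0.51,3.84,-0.06,train,B
53,5,19,1\1,3.67,3.56,0.11,3.91,-0.24,train,C
54,6,19,1\1,4.25,3.02,1.23,3.88,0.37,train,D
55,7,19,1\1,4.14,3.38,0.76,3.95,0.19,test,E
56,8,19,1\1,4.08,3.72,0.36,4.06,0.02,train,A
57,9,19,1\1,4.26,3.68,0.58,4.08,0.18,train,B
58,10,19,1\1,4.36,3.80,0.56,3.95,0.41,train,C
59,13,19,1\1,4.50,3.99,0.51,4.49,0.01,train,D
60,25,35,1\1,5.08,4.42,0.66,5.10,-0.02,train,E
61,26,35,1\1,4.85,4.75,0.10,5.31,-0.46,train,A
62,27,35,1\1,5.50,4.75,0.75,5.50,0.00,train,B
63,28,35,1\1,5.42,4.58,0.84,5.24,0.18,train,C
64,29,35,1\1,5.45,4.85,0.60,5.96,-0.51,test,D
65,30,35,1\1,6.01,4.75,1.26,5.69,0.32,train,E
66,31,35,1\1,5.73,4.66,1.07,5.66,0.07,test,A
67,27,35,13396\1,3.49,3.94,-0.45,3.58,-0.09,train,B
68,27,35,8587\1,3.49,3.94,-0.45,3.58,-0.09,train,C
69,27,35,2747\1,3.49,3.94,-0.45,3.59,-0.10,train,D
70,27,35,858\1,3.51,3.94,-0.43,3.59,-0.08,test,E
71,27,35,274\1,3.55,3.95,-0.40,3.60,-0.05,train,A
72,27,35,85\1,3.67,3.96,-0.29,3.65,0.02,train,B
73,27,35,27\1,3.92,4.00,-0.08,3.77,0.15,train,C
74,27,35,15\1,4.08,4.04,0.04,3.91,0.17,train,D
75,27,35,4\1,4.52,4.26,0.26,4.57,-0.05,train,E
76,27,35,1\6,5.34,5.32,0.02,5.58,-0.24,train,A
77,27,35,1\21,5.43,5.48,-0.05,5.42,0.01,train,B
78,27,35,1\37,5.45,5.51,-0.06,5.38,0.07,train,C
79,27,35,1\116,5.46,5.54,-0.08,5.34,0.12,train,D
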