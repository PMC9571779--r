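index,name,chem_class,pEC50_exp,pEC50_pred_mlr,resid_mlr,pEC50_pred_rbfnn,resid_rbfnn,split
1,Acetaldehyde,AHS,2.36,2.74,-0.38,2.70,-0.34,train
2,Propionaldehyde,AHS,2.72,2.81,-0.09,2.74,-0.02,test
3,Butyraldehyde,AHS,3.25,2.82,0.43,2.76,0.49,train
4,Valeraldehyde,AHS,3.27,2.81,0.46,2.75,0.52,train
5,Benzaldehyde,AHS,3.43,4.27,-0.84,4.17,-0.74,train
6,p-Nitrobenzaldehyde,AHS,4.28,4.17,0.11,4.17,0.11,train
7,p-Terephthaldehyde,AHS,4.31,4.43,-0.12,4.27,0.04,train
8,p-Chlorobenzaldehyde,AHS,4.25,4.25,0.00,4.00,0.25,test
9,p-Bromobenzaldehyde,AHS,4.30,4.31,-0.01,4.06,0.24,train
10,p-Hydrobenzaldehyde,AHS,4.54,4.09,0.45,3.98,0.56,train
11,p-Methylbenzaldehyde,AHS,3.82,3.93,-0.11,3.93,-0.11,train
12,p-Methoxybenzaldehyde,AHS,4.03,4.41,-0.38,4.31,-0.28,train
13,p-Dimethylaminobenzaldehyde,AHS,5.40,5.02,0.38,4.75,0.65,train
14,Malononitrile,CGS,2.55,2.16,0.39,2.13,0.42,train
15,Glycolonitrile,CGS,2.98,2.87,0.11,3.01,-0.03,train
16,alpha-Hydroxyisobutyronitrile,CGS,3.61,3.39,0.22,3.74,-0.13,train
17,Allyl cyanide,CGS,1.45,2.14,-0.69,2.32,-0.87,test
18,Benzonitrile,CGS,3.48,3.57,-0.09,3.69,-0.21,test
19,Benzyl cyanide,CGS,4.23,3.18,1.05,3.09,1.14,train
20,Acetonitrile,CGS,0.75,0.92,-0.17,0.92,-0.17,train
21,Acrylonitrile,CGS,1.51,1.68,-0.17,1.69,-0.18,train
22,Succinonitrile,CGS,0.36,0.85,-0.49,0.91,-0.55,train
23,Phthalonitrile,CGS,3.51,3.83,-0.32,4.05,-0.54,train
24,Lactonitrile,CGS,2.01,2.36,-0.35,2.82,-0.81,test
25,Sulfamethazine,SAS,4.08,4.33,-0.25,4.37,-0.29,train
26,Sulfapyridine,SAS,3.84,4.52,-0.68,4.57,-0.73,train
27,Sulfamethoxazole,SAS,4.45,4.69,-0.24,4.70,-0.25,train
28,Sulfadiazine,SAS,4.50,4.32,0.18,4.39,0.11,train
29,Sulfisoxazole,SAS,4.43,4.54,-0.11,4.57,-0.14,train
30,Sulfamonomethoxine,SAS,5.05,4.58,0.47,4.60,0.45,train
31,Sulfachloropyridazine,SAS,4.78,4.54,0.24,4.56,0.22,train
32,Sulfachinoxalin,SAS,4.53,4.56,-0.03,4.58,-0.05,test
33,Sulfamethoxydiazine,SAS,4.41,4.37,0.04,4.43,-0.02,test
34,Sulfamethoxypyridazine,SAS,4.36,4.40,-0.04,4.49,-0.13,train
35,Trimethoprim,TMP,3.22,3.40,-0.18,3.58,-0.36,train
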