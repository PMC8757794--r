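s_mm,x_mm,y_mm,z_mm,radius_mm
0,0,0,0,1.8
1,0.999850006749855,0.0149988750337486,0,1.796
2,1.99880021598149,0.0599820021598603,0,1.792
3,2.9959516399337,0.134908899600191,0,1.788
4,3.99040690963065,0.239712138204458,0,1.784
5,4.98127108245331,0.374297402131925,0,1.78
6,5.96765244752747,0.538543573729285,0,1.776
7,6.94866332820332,0.732302842528391,0,1.772
8,7.92342088090449,0.955400838265678,0,1.768
9,8.8910478896277,1.20763678780365,0,1.764
10,9.85067355537799,1.48878369581313,0,1.76
11,10.8014342798289,1.79858854905377,0,1.756
12,11.742474442503,2.13677254406884,0,1.752
13,12.672947170772,2.50303133808956,0,1.748
14,13.5920151019857,2.89703532292306,0,1.744
15,14.498851137041,3.31842992157744,0,1.74
16,15.3926391847161,3.7668359073572,0,1.736
17,16.2725748960969,4.24184974514162,0,1.732
18,17.1378663884371,4.74304395453919,0,1.728
19,17.987734957799,5.26996749459104,0,1.724
20,18.8214157798345,5.82214616967739,0,1.72
21,19.6381585980757,6.39908305626161,0,1.716
22,20.4372283991145,7.00025895008783,0,1.712
23,21.2179060740656,7.62513283342978,0,1.708
24,21.9794890657158,8.27314236197017,0,1.704
25,22.7212920007778,8.94370437087264,0,1.7
26,23.4426473066803,9.63621539959075,0,1.696
27,24.1429058123381,10.3500522349418,0,1.692
28,24.821437332362,11.0845724719564,0,1.688
29,25.4776312341835,11.839115092,0,1.684
30,26.1108969875828,12.6130010576445,0,1.68
31,26.7206646961259,13.4055339237567,0,1.676
32,27.3063856100333,14.2160004642514,0,1.672
33,27.8675326200174,15.0436713139471,0,1.668
34,28.4036007316454,15.887801624945,0,1.664
35,28.9141075198006,16.7476317369424,0,1.66
36,29.3985935628316,17.6223878608753,0,1.656
37,29.8566228560016,18.5112827752764,0,1.652
38,30.2877832038628,19.4135165347214,0,1.648
39,30.6916865912045,20.3282771897257,0,1.644
40,31.0679695322409,21.2547415174442,0,1.64
41,31.4162933977233,22.1920757625166,0,1.636
42,31.7363447196839,23.1394363873904,0,1.632
43,32.0278354735358,24.0959708314481,0,1.628
44,32.2905033372755,25.0608182782542,0,1.624
45,32.5241119275553,26.0331104302319,0,1.62
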