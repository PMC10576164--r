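time,rep1,rep2,rep3
0,-0.033834428548409519,-0.10864355198395879,0.50431118221030158
3,1.134413875578940578,1.42155539678849707,0.96963613689237327
6,1.397138025646979420,1.48759118648035926,1.92036454930465639
9,1.993306062340873153,2.72688921703419940,1.93397984328424299
12,2.793131713343836697,2.49491968617294635,2.47277062986817331
15,2.176560485403210787,2.05967993334224397,2.40810650417536110
18,1.155428959599005490,1.23233886905619716,1.36894486820161809
21,-0.826418847348393992,0.30602078987853942,-0.63690852627064765
24,-3.214413496224544531,-2.45286248963976394,-1.91841310974016821
27,-2.641833841052546816,-2.82875990092797291,-2.50938684142960478
30,-0.807163818742481221,0.27721822752139491,-0.25822390394484374
33,2.369242115220324685,2.49350486679888927,1.46937717270616419
36,1.088870819543329649,0.11206758937754346,0.65490839312583948
39,-2.992349237102689408,-1.87188338755211570,-2.36103859852746201
42,2.451214700393705481,2.80898510051615879,2.53098785022788997
45,-2.634914222187035637,-2.93125539616258735,-2.56574072747356396
48,-1.733199377770397565,-2.64699755820302407,-1.90556010010719068
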