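s_mm,r_mm
0,1.3999999999957382
0.82051282051282048,1.3871794871050358
1.641025641025641,1.3743589732598784
2.4615384615384617,1.36153844782763
3.2820512820512819,1.3487178041882018
4.1025641025641022,1.3358961484923872
4.9230769230769234,1.3230672327834867
5.7435897435897436,1.3101947760760657
6.5641025641025639,1.2971046378189628
7.3846153846153841,1.2831109382342407
8.2051282051282044,1.2660212885747213
9.0256410256410255,1.2402514309806649
9.8461538461538467,1.1948487127310841
10.666666666666666,1.1145362819058728
11.487179487179487,0.98807471520748502
12.307692307692308,0.82339722645595281
13.128205128205128,0.65799190606606339
13.948717948717949,0.5482644658310325
14.769230769230768,0.53701994036291834
15.589743589743591,0.62352684898688227
16.410256410256409,0.76405386399597019
17.23076923076923,0.90235526778585662
18.051282051282051,1.0017930559647206
18.871794871794872,1.0552162299608305
19.692307692307693,1.0741853456882373
20.512820512820515,1.0739272660180215
21.333333333333332,1.0652253343431797
22.153846153846153,1.0535304344726832
22.974358974358974,1.0409672053843333
23.794871794871796,1.0281959893397461
24.615384615384617,1.0153834077293598
25.435897435897434,1.0025639677211711
26.256410256410255,0.98974357702186122
27.076923076923077,0.97692307590894401
27.897435897435898,0.96410256403425598
28.717948717948715,0.95128205127816379
29.538461538461537,0.9384615384613515
30.358974358974358,0.92564102564101813
31.179487179487182,0.91282051282051258
32,0.90000000000000013
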