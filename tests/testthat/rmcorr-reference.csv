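dataset,r_rm,df,p
1,0.573453446122082,29,0.0007451775350906524
2,0.3317675862772044,15,0.1932790862649891
3,0.4341483321168911,41,0.0036284801407452452
4,0.3774331134196247,35,0.021281564580813896
5,0.19337856234290843,34,0.25846349846700634
6,0.12602700921852086,19,0.5862056264539549
7,0.2596094591890366,9,0.44075581974214284
8,0.42089403884845217,48,0.0023372581856944312
9,0.4480736161867136,23,0.02468673126345964
10,0.4977521469336816,41,0.0006831849023016636
11,0.5000033892661064,35,0.0016263547434833769
12,0.5537379739523407,34,0.0004592755738985324
13,0.18861583099379267,29,0.309548214234073
14,0.6040967229476238,26,0.0006636415554708323
15,0.38542834384791763,23,0.05707421951666044
16,0.5795817271540465,48,1.0316321082177787e-05
17,0.5235462336381018,35,0.0008833898938338361
18,0.3592507869543641,13,0.18847945504464925
19,0.06734048114597409,11,0.8269762717501459
20,0.4445305657104284,59,0.0003318124531751273
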