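age,annual_death_prob
40,0.00299192524878888
41,0.00325692737877215
42,0.00354535963353186
43,0.00385928585206186
44,0.00420095023417333
45,0.0045727928367284
46,0.00497746635177299
47,0.00541785426327901
48,0.00589709048468923
49,0.00641858058486533
50,0.00698602471527865
51,0.00760344235620924
52,0.00827519900417328
53,0.00900603492658758
54,0.00980109611255209
55,0.0106659675502887
56,0.0116067089618699
57,0.0126298931239599
58,0.0137426468988679
59,0.0149526950926658
60,0.0162684072457109
61,0.0176988474447985
62,0.0192538272243193
63,0.0209439615950352
64,0.0227807282020379
65,0.0247765295665009
66,0.0269447583071231
67,0.0292998651645716
68,0.0318574295633007
69,0.0346342323371021
70,0.0376483301144989
71,0.0409191307041353
72,0.0444674686347749
73,0.0483156797851756
74,0.0524876737813795
75,0.0570090025380259
76,0.0619069229711423
77,0.0672104515074891
78,0.0729504075551068
79,0.079159442576987
80,0.0858720508214187
81,0.0931245571067996
82,0.100955076336024
83,0.109403438629724
84,0.118511073126843
85,0.128320842619368
86,0.138876820287474
87,0.150223998913621
88,0.162407922123556
89,0.175474226488298
90,0.189468082801986
91,0.204433524625643
92,0.220412652381005
93,0.237444702043707
94,0.255564969002808
95,0.274803580134651
96,0.295184110821092
97,0.316722048782655
98,0.339423113461825
99,0.363281448533986
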