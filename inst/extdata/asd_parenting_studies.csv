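study,sample,relationship,r,n,rel_x,rel_y,role,ss_measure,qol_focus,culture,child_age,pub_status
Akram,Akram-1,SS-PS,-0.53,339,,,mother,MSPSS,not_applicable,east,,published
Ban & Sun,Ban-1,SS-PS,-0.238,245,,,both,other,not_applicable,east,,published
Bohadana,Bohadana-1,SS-PS,-0.53,139,,,both,MSPSS,not_applicable,west,8.90,published
Bohadana,Bohadana-1,SS-QoL,0.62,139,,,both,MSPSS,OQoL,west,8.90,published
Chu,Chu-1,PS-QoL,-0.57,110,,,both,not_applicable,OQoL,east,,published
Drogomyretska,Drogomyretska-1,SS-PS,-0.133,454,,,not_reported,MSPSS,not_applicable,west,8.17,published
Falk,Falk-1,SS-PS,-0.26,229,,,father,other,not_applicable,west,8.38,published
Falk,Falk-2,SS-PS,-0.23,250,,,mother,other,not_applicable,west,8.38,published
Hall & Graff,Hall-1,SS-PS,-0.252,73,,,both,FSS,not_applicable,west,8.00,published
Henry,Henry-1,PS-QoL,-0.743,115,,,mother,not_applicable,OQoL,west,,unpublished
Gu,Gu-1,SS-PS,-0.512,115,,,both,other,not_applicable,east,,unpublished
Hsiao (a),HsiaoA-1,SS-PS,-0.155,429,,,not_reported,other,not_applicable,west,,published
Hsiao (a),HsiaoA-1,SS-QoL,0.374,429,,,not_reported,other,HQoL,west,,published
Hsiao (a),HsiaoA-1,PS-QoL,-0.33,429,,,not_reported,not_applicable,HQoL,west,,published
Hsiao (b),HsiaoB-1,PS-QoL,-0.494,236,,,both,not_applicable,FQoL,west,,published
Khanna,Khanna-1,SS-PS,-0.38,304,,,both,MSPSS,not_applicable,west,,unpublished
Khanna,Khanna-1,SS-QoL,0.391,304,,,both,MSPSS,HQoL,west,,unpublished
Khanna,Khanna-1,PS-QoL,-0.472,304,,,both,not_applicable,HQoL,west,,unpublished
Kuru & Piyal,Kuru-1,SS-QoL,0.524,90,,,both,MSPSS,OQoL,west,,published
Lei & Kantor,Lei-1,SS-QoL,0.424,163,,,both,other,FQoL,east,,published
Li,Li-1,SS-QoL,0.407,211,,,not_reported,other,FQoL,east,,unpublished
Liu (a),LiuA-1,SS-PS,-0.561,95,,,mother,other,not_applicable,east,4.75,published
Liu (b),LiuB-1,SS-PS,-0.26,1384,,,both,FSS,not_applicable,east,5.74,unpublished
Liu (b),LiuB-1,SS-QoL,0.44,1384,,,both,FSS,FQoL,east,5.74,unpublished
Liu (b),LiuB-1,PS-QoL,-0.49,1384,,,both,not_applicable,FQoL,east,5.74,unpublished
Lu,Lu-1,SS-PS,-0.322,479,,,both,MSPSS,not_applicable,east,6.68,published
Pozo,Pozo-1,SS-QoL,0.296,118,,,mother,other,FQoL,west,12.40,published
Rutstein,Rutstein-1,SS-PS,-0.61,25,,,mother,FSS,not_applicable,west,4.30,unpublished
Singh,Singh-1,SS-PS,-0.481,70,,,mother,MSPSS,not_applicable,east,8.01,published
Tomeny,Tomeny-1,SS-PS,-0.15,115,,,both,other,not_applicable,west,12.03,unpublished
Wang (a),WangA-1,SS-PS,-0.16,150,,,mother,other,not_applicable,east,5.15,published
Wang (b),WangB-1,SS-QoL,0.52,625,,,both,other,FQoL,east,4.66,unpublished
Weinberg,Weinberg-1,SS-PS,-0.48,105,,,both,MSPSS,not_applicable,east,9.36,published
Weinberg,Weinberg-2,SS-PS,-0.35,104,,,both,MSPSS,not_applicable,east,6.80,published
Zaidman,Zaidman-1,SS-PS,-0.57,283,,,mother,other,not_applicable,west,3.24,published
Zeng (a),ZengA-1,SS-PS,-0.237,219,,,mother,FSS,not_applicable,east,10.30,published
Zeng (a),ZengA-1,SS-QoL,0.533,219,,,mother,FSS,FQoL,east,10.30,published
Zeng (a),ZengA-1,PS-QoL,-0.381,219,,,mother,not_applicable,FQoL,east,10.30,published
Zeng (a),ZengA-2,SS-PS,-0.239,219,,,father,FSS,not_applicable,east,10.30,published
Zeng (a),ZengA-2,SS-QoL,0.594,219,,,father,FSS,FQoL,east,10.30,published
Zeng (a),ZengA-2,PS-QoL,-0.360,219,,,father,not_applicable,FQoL,east,10.30,published
Zeng (b),ZengB-1,SS-PS,-0.238,226,,,not_reported,FSS,not_applicable,east,10.30,published
Zeng (b),ZengB-1,SS-QoL,0.531,226,,,not_reported,FSS,FQoL,east,10.30,published
Zeng (b),ZengB-1,PS-QoL,-0.384,226,,,not_reported,not_applicable,FQoL,east,10.30,published
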