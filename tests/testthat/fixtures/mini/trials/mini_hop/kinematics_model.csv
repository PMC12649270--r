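frame,FE,AA,IE,ML,AP,IS,speed,method,specimen,trial,motion
1,54.01637559,-0.2593998992251,-0.4821323661,-1.7448976616,-2.851664827,-41.33351542,0.7601707098,model,specimen2,mini_hop,hop
2,54.04075472,-0.1449014117937,-0.4704662242,-1.5766665964,-3.220649761,-41.16377062,0.7684245829,model,specimen2,mini_hop,hop
3,54.09055145,-0.0360642242616,-0.4666080920,-1.4151417480,-3.520982066,-41.00269493,0.7808876926,model,specimen2,mini_hop,hop
4,54.15302437,0.0553497388203,-0.4678204540,-1.2712585327,-3.756218225,-40.85742568,0.7863697776,model,specimen2,mini_hop,hop
5,54.22121174,0.1190592672257,-0.4719831415,-1.1543924977,-3.932162836,-40.73654714,0.7871506745,model,specimen2,mini_hop,hop
6,54.29391118,0.1502949359688,-0.4781607252,-1.0703444000,-4.052147738,-40.64623976,0.7856275084,model,specimen2,mini_hop,hop
7,54.37381440,0.1525592410701,-0.4878784796,-1.0182825986,-4.113393657,-40.58705849,0.7840300322,model,specimen2,mini_hop,hop
8,54.46304332,0.1346898244795,-0.5040840605,-0.9906419347,-4.114074785,-40.55415990,0.7837231424,model,specimen2,mini_hop,hop
9,54.55830213,0.1053780708812,-0.5283311477,-0.9774253963,-4.063878622,-40.53990447,0.7848827107,model,specimen2,mini_hop,hop
10,54.65276603,0.0706505158214,-0.5600561562,-0.9706584906,-3.981151150,-40.53705642,0.7867392096,model,specimen2,mini_hop,hop
11,54.74115803,0.0342200743608,-0.5973849073,-0.9668482773,-3.883345877,-40.54130723,0.7879784960,model,specimen2,mini_hop,hop
12,54.82004364,-0.0007903650395,-0.6369070959,-0.9673841130,-3.784439158,-40.55132482,0.7871206765,model,specimen2,mini_hop,hop
13,54.88597580,-0.0304457869114,-0.6733273154,-0.9761311706,-3.696337246,-40.56662496,0.7827187202,model,specimen2,mini_hop,hop
14,54.93607183,-0.0507619521259,-0.7007506780,-0.9966964575,-3.628490821,-40.58737198,0.7732446514,model,specimen2,mini_hop,hop
15,54.96921839,-0.0591706947331,-0.7143508734,-1.0314463594,-3.585871480,-40.61594254,0.7569594959,model,specimen2,mini_hop,hop
16,54.98570614,-0.0545318866763,-0.7109310614,-1.0810952637,-3.568200019,-40.65602535,0.7319685037,model,specimen2,mini_hop,hop
17,54.98642712,-0.0365046406320,-0.6892441336,-1.1449640155,-3.572054288,-40.70983798,0.6963043750,model,specimen2,mini_hop,hop
18,54.97288551,-0.0059664596637,-0.6506223420,-1.2215833025,-3.593875975,-40.77603248,0.6480067338,model,specimen2,mini_hop,hop
19,54.94810630,0.0340033634547,-0.5993468403,-1.3073338823,-3.630380549,-40.84928259,0.5853651671,model,specimen2,mini_hop,hop
20,54.91695864,0.0783904937376,-0.5418621670,-1.3951990340,-3.675977882,-40.92298976,0.5502768006,model,specimen2,mini_hop,hop
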