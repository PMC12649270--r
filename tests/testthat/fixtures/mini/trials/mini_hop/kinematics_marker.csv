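frame,FE,AA,IE,ML,AP,IS,speed,method,specimen,trial,motion
1,54.92580622,0.42224546443,-0.2448255295,-0.7461549532,-3.381002343,-41.09714877,0.7278424042,marker,specimen2,mini_hop,hop
2,54.92765216,0.36748124685,-0.2935286254,-0.7656907960,-3.365784728,-41.09077655,0.7375046305,marker,specimen2,mini_hop,hop
3,54.92839944,0.31561215393,-0.3390527363,-0.7851341965,-3.348458529,-41.08296369,0.7537349086,marker,specimen2,mini_hop,hop
4,54.92712860,0.26888683353,-0.3792995089,-0.8032381029,-3.330913472,-41.07435394,0.7645631421,marker,specimen2,mini_hop,hop
5,54.92343314,0.22853394706,-0.4133522236,-0.8196089767,-3.315022423,-41.06569872,0.7714748459,marker,specimen2,mini_hop,hop
6,54.91752418,0.19484411172,-0.4409471211,-0.8344233366,-3.301918229,-41.05762604,0.7757515294,marker,specimen2,mini_hop,hop
7,54.91010001,0.16743452581,-0.4622584425,-0.8480563630,-3.291561926,-41.05053740,0.7784444755,marker,specimen2,mini_hop,hop
8,54.90209566,0.14560824005,-0.4780127686,-0.8606192705,-3.283288208,-41.04480268,0.7803459789,marker,specimen2,mini_hop,hop
9,54.89432431,0.12862692668,-0.4893719608,-0.8717442462,-3.276825024,-41.04090828,0.7818956475,marker,specimen2,mini_hop,hop
10,54.88747992,0.11580884621,-0.4976351358,-0.8808837225,-3.272632439,-41.03934167,0.7830958733,marker,specimen2,mini_hop,hop
11,54.88247994,0.10663566897,-0.5039345879,-0.8877499348,-3.271366550,-41.04041971,0.7835055622,marker,specimen2,mini_hop,hop
12,54.88062048,0.10101434626,-0.5089886800,-0.8924946554,-3.273103128,-41.04415835,0.7822554043,marker,specimen2,mini_hop,hop
13,54.88335901,0.09914035889,-0.5132586203,-0.8956909222,-3.277135679,-41.05025676,0.7780293867,marker,specimen2,mini_hop,hop
14,54.89183800,0.10087810839,-0.5175338499,-0.8984548226,-3.282640766,-41.05829229,0.7690915893,marker,specimen2,mini_hop,hop
15,54.90659699,0.10567562625,-0.5231860419,-0.9025491892,-3.289421786,-41.06795176,0.7534204337,marker,specimen2,mini_hop,hop
16,54.92761132,0.11303494167,-0.5316466100,-0.9099340241,-3.297903500,-41.07905327,0.7288525004,marker,specimen2,mini_hop,hop
17,54.95417607,0.12248871718,-0.5437490495,-0.9220188611,-3.308580853,-41.09136316,0.6931995421,marker,specimen2,mini_hop,hop
18,54.98486498,0.13318651932,-0.5594935273,-0.9392083806,-3.321508370,-41.10446879,0.6444754183,marker,specimen2,mini_hop,hop
19,55.01790073,0.14400155964,-0.5780429880,-0.9606959469,-3.336059085,-41.11782958,0.5812912701,marker,specimen2,mini_hop,hop
20,55.05106178,0.15409049435,-0.5978109174,-0.9844299664,-3.351058135,-41.13073951,0.5459625144,marker,specimen2,mini_hop,hop
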