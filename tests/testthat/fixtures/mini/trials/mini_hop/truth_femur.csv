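frame_index,m11,m12,m13,m14,m21,m22,m23,m24,m31,m32,m33,m34,m41,m42,m43,m44
1,0.999192859576,-0.0401355780898,0.00166275211918,-28.2747335389,0.0401419198785,0.999186083526,-0.00397451340755,0,-0.0015018793846,0.00403805147946,0.999990719206,1.30178530602,0,0,0,1
2,0.999215185608,-0.0395759046714,0.00166151135287,-25.2984457979,0.0395821109694,0.999208767542,-0.00388527467893,0,-0.00150643345084,0.00394799158619,0.99999107197,1.26391193803,0,0,0,1
3,0.999239444451,-0.0389586496976,0.00166020092481,-22.322158057,0.0389647062247,0.999233411866,-0.003786856185,0,-0.00151139743092,0.00384866531182,0.99999145169,1.22284581879,0,0,0,1
4,0.999265469636,-0.038285368483,0.00165884091191,-19.3458703161,0.0382912612379,0.999259846359,-0.00367950634468,0,-0.00151674185853,0.00374032274626,0.999991854707,1.17869068489,0,0,0,1
5,0.999293083976,-0.037557757767,0.00165745251305,-16.3695825751,0.0375634730566,0.999287889943,-0.00356349614759,0,-0.00152243529933,0.00362323672788,0.999992277143,1.13155807601,0,0,0,1
6,0.999322101138,-0.0367776514959,0.00165605781618,-13.3932948342,0.0367831759656,0.999317352211,-0.00343911847573,0,-0.00152844461122,0.00349770216729,0.999992714942,1.08156705323,0,0,0,1
7,0.999352327289,-0.0359470162586,0.00165467955494,-10.4170070933,0.0359523369218,0.999348035115,-0.00330668736966,0,-0.00153473521733,0.00336403531534,0.999993163904,1.02884389821,0,0,0,1
8,0.999383562803,-0.0350679463843,0.00165334085721,-7.44071935233,0.035073050653,0.999379734715,-0.00316653724078,0,-0.00154127138909,0.00322257297707,0.999993619733,0.973521794213,0,0,0,1
9,0.999415604009,-0.0341426587162,0.00165206498835,-4.4644316114,0.0341475344313,0.99941224297,-0.00301902203158,0,-0.00154801653666,0.00307367167328,0.999994078076,0.915740489671,0,0,0,1
10,0.999448244967,-0.0331734870703,0.00165087509155,-1.48814387047,0.0331781225323,0.999445349553,-0.00286451432587,0,-0.00155493350399,0.00291770675175,0.99999453457,0.855645945177,0,0,0,1
11,0.999481279245,-0.0321628763949,0.00164979392825,1.48814387047,0.0321672603943,0.99947884368,-0.00270340441108,0,-0.0015619848658,0.00275507144999,0.99999498488,0.793389964765,0,0,0,1
12,0.9995145017,-0.0311133766424,0.00164884362107,4.4644316114,0.0311174984904,0.999512515924,-0.00253609929491,0,-0.0015691332235,0.0025861759119,0.999995424747,0.729129812446,0,0,0,1
13,0.999547710217,-0.030027636369,0.00164804540208,7.44071935233,0.030031485928,0.999546160005,-0.00236302167878,0,-0.00157634149746,0.00241144616052,0.999995850029,0.663027814941,0,0,0,1
14,0.99958070742,-0.0289083960785,0.00164741936891,10.4170070933,0.0289119637917,0.999579574538,-0.00218460889048,0,-0.00158357321278,0.00223132302932,0.99999625674,0.595250951633,0,0,0,1
15,0.999613302311,-0.0277584813247,0.00164698425135,13.3932948342,0.0277617582462,0.999612564712,-0.00200131177888,0,-0.00159079277589,0.00204626105487,0.999996641091,0.52597043276,0,0,0,1
16,0.999645311846,-0.0265807955909,0.0016467571908,16.3695825751,0.0265837734151,0.999644943902,-0.00181359357333,0,-0.00159796573956,0.0018567273332,0.99999699953,0.455361266926,0,0,0,1
17,0.999676562411,-0.0253783129644,0.0016467535349,19.3458703161,0.0253809840542,0.999676535183,-0.00162192871065,0,-0.00160505905364,0.00166320034315,0.999997328771,0.383601819012,0,0,0,1
18,0.999706891197,-0.0241540706236,0.00164698664949,22.322158057,0.0241564280381,0.999707172737,-0.00142680163286,0,-0.0016120412995,0.00146616873922,0.999997625833,0.310873359611,0,0,0,1
19,0.999736147463,-0.0229111611568,0.00164746774994,25.2984457979,0.0229131986785,0.999736703142,-0.00122870555864,0,-0.00161888290579,0.00126613011743,0.999997888064,0.237359607123,0,0,0,1
20,0.999764193662,-0.0216527247345,0.00164820575351,28.2747335389,0.0216544368943,0.999764986529,-0.00102814123165,0,-0.00162555634387,0.00106358975691,0.99999811317,0.163246263668,0,0,0,1
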