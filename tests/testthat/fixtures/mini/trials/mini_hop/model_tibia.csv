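frame_index,m11,m12,m13,m14,m21,m22,m23,m24,m31,m32,m33,m34,m41,m42,m43,m44
1,0.99781973989,0.0653695334238,0.00908794725367,-29.0712258416,-0.0272512995242,0.533497667424,-0.845362410761,-2.18832139174,-0.060109345027,0.843271642446,0.534115908476,-40.4315476742,0,0,0,1
2,0.997672774661,0.0681690172201,-0.00142119344777,-25.4145467999,-0.0378533863306,0.536417888189,-0.843103178961,-3.02971570259,-0.056711161537,0.841194884865,0.537749951032,-40.0403561059,0,0,0,1
3,0.997792153832,0.0656674914223,0.00992966871677,-23.1550888658,-0.0264089579286,0.529487033966,-0.847906862693,-3.08232441793,-0.06093754747,0.845772582573,0.530052218066,-41.0232671654,0,0,0,1
4,0.998100347236,0.0611744108346,0.00730673024942,-19.7117326396,-0.0263361098907,0.530863043672,-0.847048309236,-3.17339695496,-0.0556965543254,0.845246780723,0.53146568423,-39.3241044359,0,0,0,1
5,0.997206492932,0.0714572178202,0.0217503212576,-16.2569617046,-0.0208517019697,0.545933012672,-0.837569311878,-3.14864779387,-0.0717245911692,0.834776024869,0.545897949552,-39.2628368251,0,0,0,1
6,0.997238939359,0.0741194656224,0.00456099137826,-13.0579391126,-0.0353721790401,0.528123072168,-0.848430804246,-2.3659864814,-0.0652940026071,0.845926903142,0.529286659348,-38.8938946015,0,0,0,1
7,0.99801987954,0.0628967139404,-0.00056869963751,-10.9520431086,-0.0342974539544,0.536594739993,-0.843142793164,-3.63917937843,-0.0527257498384,0.841492773818,0.53768941492,-40.0472493038,0,0,0,1
8,0.99774294459,0.0670959554851,0.00267381333237,-8.33603785109,-0.0335223734712,0.532202459383,-0.845953185882,-3.19545941066,-0.0581830473338,0.843954190098,0.533250464621,-39.7925910555,0,0,0,1
9,0.997599279209,0.0691314169733,-0.00406513335063,-5.05996769287,-0.0399772508347,0.526970402101,-0.84894288072,-3.10471915124,-0.0565464193172,0.847067318751,0.528468977298,-39.4202602034,0,0,0,1
10,0.997491585245,0.0707677444064,-0.00156962297428,-2.66563500726,-0.0387443176607,0.527285822246,-0.848804182075,-2.90031259517,-0.0592403174675,0.846735843112,0.528705018679,-40.8377265835,0,0,0,1
11,0.997908357862,0.0640583106028,0.00868574417974,0.934488999256,-0.0272141374246,0.538167092986,-0.842398700588,-3.17257803335,-0.0586370193092,0.840400328933,0.538784731685,-39.291922439,0,0,0,1
12,0.997564065596,0.0697135612465,-0.00244016606052,4.29946689726,-0.0391991573755,0.531297077999,-0.846278229054,-2.75475807998,-0.057700616055,0.844312403254,0.532735586026,-39.98704494,0,0,0,1
13,0.996734507804,0.0802206672478,-0.00921767322467,6.78675532701,-0.0499473528487,0.522809788038,-0.850984833869,-3.52638247724,-0.0634474814059,0.848666347912,0.525109366727,-41.0025835257,0,0,0,1
14,0.99721054831,0.0744752566261,-0.00495565224653,10.2807603917,-0.0438401517603,0.530689551908,-0.846431710529,-2.55435382987,-0.060408305988,0.844287886711,0.532474225593,-40.6298004717,0,0,0,1
15,0.997358843734,0.072608537796,-0.00182676331465,12.9664175856,-0.0403864102565,0.533496842554,-0.844837296082,-3.37922103524,-0.0603678282836,0.842679725177,0.535020192221,-40.5393303617,0,0,0,1
16,0.99663747436,0.0815716372694,-0.00773386676972,16.318306269,-0.04994040861,0.529903520109,-0.846586212364,-3.16165517082,-0.0649592202069,0.844125776985,0.532195426831,-40.0070350008,0,0,0,1
17,0.996983159778,0.0760018989608,-0.0157572356075,18.7038448525,-0.0539183230757,0.532111641025,-0.844955629558,-3.62066277344,-0.0558336238869,0.843256137149,0.534604240167,-40.539229871,0,0,0,1
18,0.997059812327,0.0766234182593,0.000763162170672,21.9495733014,-0.0400103246169,0.529075413489,-0.847631040469,-3.55889922135,-0.0653521580844,0.845108311766,0.530585560318,-40.8906399419,0,0,0,1
19,0.997376686264,0.0717870315122,-0.00929342799275,24.4631507154,-0.0462645208661,0.533441731296,-0.844570608902,-3.37455944777,-0.0556717145974,0.842784991216,0.535363538892,-41.8547285797,0,0,0,1
20,0.997254577374,0.0736454851675,-0.00772336852716,27.911128523,-0.0458550034873,0.532284832226,-0.845322527818,-3.66484400338,-0.0581431557635,0.843355915315,0.534200499383,-40.1302907249,0,0,0,1
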