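frame_index,m11,m12,m13,m14,m21,m22,m23,m24,m31,m32,m33,m34,m41,m42,m43,m44
1,0.998944844083,-0.0452407021558,0.00790426137522,-27.6257170852,0.0453689743062,0.998827641183,-0.016881924626,-0.0782565781858,-0.00713124462089,0.0172227197946,0.999826246541,0.91479321127,0,0,0,1
2,0.999249980546,-0.038396854673,0.00501576805547,-24.5056344462,0.0384528308502,0.999193247021,-0.0115859789225,0.343906985098,-0.00456685642072,0.0117701596935,0.999920300406,1.12408096508,0,0,0,1
3,0.999154970315,-0.0410908822823,-0.000940578465552,-22.3829083981,0.0410899448661,0.999154955984,-0.00099516965738,0.441776939328,0.000980676034591,0.000955680392186,0.999999062474,1.18054956584,0,0,0,1
4,0.999254960594,-0.038380803858,0.00405433384068,-19.2366786915,0.038388687327,0.999261105051,-0.00188483896182,0.413450594339,-0.00397899647939,0.00203907523665,0.99999000483,0.46435602324,0,0,0,1
5,0.999553218655,-0.027715052994,-0.0111910193079,-16.6051051609,0.0276186969823,0.999580889871,-0.00867480148105,-0.53687481545,0.0114267516211,0.00836184437039,0.999899749428,1.08664104804,0,0,0,1
6,0.999538427216,-0.0289129970801,-0.00932583074865,-14.5713334046,0.0290755751526,0.999418788395,0.017795963945,-0.510246715763,0.00880587581401,-0.0180589037052,0.999798145902,0.767556325805,0,0,0,1
7,0.999337912006,-0.0320941726125,0.0171377277123,-9.65256647575,0.0330292557464,0.997804879248,-0.0573976586074,3.20483238159,-0.0152579779676,0.0579257026983,0.998204291253,0.340612462372,0,0,0,1
8,0.999410734672,-0.0343224858131,0.000387802743516,-7.61856999022,0.0343237804045,0.999402496817,-0.00406539733152,0.496497844003,-0.000248036487907,0.00407631259003,0.999991661042,0.894738800995,0,0,0,1
9,0.999462438677,-0.0321599339595,0.00636964059875,-4.22437424824,0.0321908774762,0.999470133967,-0.0048165044949,-0.271063046956,-0.00621136707608,0.00501895964846,0.999968113973,1.13736414829,0,0,0,1
10,0.999461622177,-0.0327449039248,0.00205841279898,-1.12873858017,0.03275209232,0.999457161522,-0.00356128221083,0.569020437038,-0.00194068156946,0.00362678222149,0.999991540067,0.750584621354,0,0,0,1
11,0.999525817455,-0.0305778187535,0.00362453331531,1.67678330132,0.0306034603977,0.99950535593,-0.00724373370983,0.124009633985,-0.00340124288492,0.00735122211951,0.999967195002,0.766568981998,0,0,0,1
12,0.999524587116,-0.0307812520469,0.00176473030396,4.15160178732,0.0307858736515,0.999522478016,-0.00265441586701,0.623680967584,-0.0016821813626,0.00270748268767,0.999994919889,0.224199444754,0,0,0,1
13,0.999550724706,-0.0299064825765,0.00198772217843,7.72209084375,0.0299106752196,0.999550339922,-0.00211411182263,-0.46438140354,-0.00192360273073,0.00217261611692,0.999995789737,0.442686941124,0,0,0,1
14,0.999530975188,-0.030248250334,0.00478257170307,10.2065568091,0.0302675949365,0.99953372523,-0.00402552154519,-0.36656028917,-0.00465857672713,0.00416839041876,0.999980460901,-0.00951916679519,0,0,0,1
15,0.999430551284,-0.0337118699596,-0.00144325496561,13.5372773579,0.0337168732911,0.999424957488,0.00359538662664,0.177654795594,0.00132121782624,-0.00364200128314,0.999992495077,-0.170337585875,0,0,0,1
16,0.99965056384,-0.0263648400142,0.00190929979807,16.3971748421,0.0263671615588,0.99965160436,-0.00120112107615,-0.153664254464,-0.00187696724134,0.00125104417726,0.999997455938,0.194789492696,0,0,0,1
17,0.999717089659,-0.0237819281028,-0.000400672526071,20.1439216667,0.0237816315958,0.999716911054,-0.000729212749025,0.546432588747,0.000417901185277,0.000719477800792,0.999999653855,-0.259677973711,0,0,0,1
18,0.999058768858,-0.0433430391082,0.00171968851537,20.666827968,0.0433240406247,0.999012345439,0.00986717613187,-0.430700943838,-0.00214566345813,-0.00978338498331,0.999949839495,-1.04823822082,0,0,0,1
19,0.999839272786,-0.017871954321,0.00142191552547,26.0646063937,0.0178779350378,0.99983088364,-0.00431086506167,-0.731788331972,-0.00134463147283,0.00433559310173,0.999989697246,0.292419037849,0,0,0,1
20,0.999764296932,-0.0216878205841,0.00099449353377,28.8433270772,0.0216891032604,0.999763921572,-0.00129766028458,-0.118406947702,-0.000966115331869,0.00131892409502,0.999998663529,0.783243427125,0,0,0,1
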