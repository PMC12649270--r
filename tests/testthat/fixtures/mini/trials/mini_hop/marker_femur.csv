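frame_index,m11,m12,m13,m14,m21,m22,m23,m24,m31,m32,m33,m34,m41,m42,m43,m44
1,0.999294301615,-0.0375177615567,0.00182107866344,-28.2551118597,0.0375249920059,0.999287223237,-0.00411344755825,0.0425434388926,-0.00166545329622,0.00417888066724,0.99998988156,1.31439203126,0,0,0,1
2,0.999285193313,-0.0377741161219,0.00148948847061,-25.2930201734,0.0377811588504,0.999273408949,-0.00502376377427,0.0575952515498,-0.00129863798544,0.00507644735484,0.999986271517,1.30595336449,0,0,0,1
3,0.999298736588,-0.0374437310481,4.53819254519e-05,-22.2742060247,0.0374437565411,0.999297552051,-0.00153868818839,0.00826275642474,1.22641796811e-05,0.00153930843243,0.999998815189,1.18252712526,0,0,0,1
4,0.999242354811,-0.0388454073627,0.00239805708037,-19.3642445774,0.0388513718299,0.99924189097,-0.00249283738955,-0.0218693908728,-0.00229940380775,0.00258411651059,0.999994017524,1.19040148525,0,0,0,1
5,0.999367648369,-0.0355194469017,0.00163471232231,-16.3589463085,0.0355223714159,0.999367267299,-0.00179615720737,-0.00656885624817,-0.00156987947582,0.0018530902627,0.999997050763,1.11732894123,0,0,0,1
6,0.999348685193,-0.0360389278674,0.00184420199313,-13.3897856874,0.0360403469855,0.999350060103,-0.000742133204324,-0.102520933244,-0.00181625768766,0.000808115521723,0.999998024077,1.10007576363,0,0,0,1
7,0.999230424612,-0.039179272999,0.00188231155198,-10.4650233623,0.0391883806424,0.999218960518,-0.00507343710814,0.0940268849775,-0.00168206781484,0.0051432974574,0.999985358462,1.06124516538,0,0,0,1
8,0.999381287767,-0.0351530196824,0.00114318323317,-7.42205968929,0.035155057967,0.999380222416,-0.00181464675604,0.0738288672223,-0.00107868440069,0.00185371268473,0.999997700092,0.906017800749,0,0,0,1
9,0.999432267722,-0.0336560292978,0.00155368187478,-4.45101748534,0.0336598833025,0.999430156223,-0.00252489357336,-0.00787241341964,-0.00146781862676,0.00257575686038,0.999995605483,0.880518281358,0,0,0,1
10,0.999462185163,-0.0327841203356,0.000736126682734,-1.47317782449,0.0327854730004,0.999460591569,-0.00190752761685,-0.0902087841174,-0.000673192994861,0.00193063598167,0.999997909726,0.816192747967,0,0,0,1
11,0.999537921788,-0.0303839047061,0.000872492045022,1.55407380032,0.0303843715662,0.999538149512,-0.000526910517915,-0.0845065368877,-0.00085607948518,0.00055317716653,0.999999480561,0.749765920628,0,0,0,1
12,0.999515060285,-0.0310461071894,0.00240488925935,4.42732355817,0.0310492061839,0.999517060234,-0.00126217914014,0.00180058820301,-0.00236454209382,0.00133623696181,0.999996311699,0.739088320691,0,0,0,1
13,0.999631145639,-0.0271428805554,0.000914715364192,7.48528539748,0.0271461445179,0.999624374359,-0.00376789407823,0.0577503719675,-0.000812100274736,0.00379133526953,0.999992483107,0.680952075244,0,0,0,1
14,0.999635428984,-0.0269904726928,0.000723535552918,10.4329794173,0.0269922838144,0.999632201557,-0.00262263688968,-0.0018456667092,-0.000652483228315,0.00264121062928,0.999996299129,0.580305948348,0,0,0,1
15,0.99960436672,-0.0280474998516,0.00210897737389,13.3944030557,0.0280505619902,0.999605473157,-0.00143666516827,-0.0124665493375,-0.00206785045961,0.00149525477628,0.999996744099,0.529222880275,0,0,0,1
16,0.999630418531,-0.0270100008782,0.00307996762417,16.3158203879,0.027013820222,0.999634333567,-0.00120526822499,-0.0318705425169,-0.00304628708758,0.00128802447188,0.999994530549,0.465427111091,0,0,0,1
17,0.999665305478,-0.0257617773502,0.0023680902623,19.3149730032,0.0257647688066,0.999667262294,-0.00124152533988,-0.0447289513118,-0.00233531841,0.00130212310627,0.999996425375,0.389716619853,0,0,0,1
18,0.999749377692,-0.0222738149061,0.00224921615277,22.2872088247,0.0222715008315,0.999751409344,0.00104869744811,-0.135044207425,-0.0022720155115,-0.000998341201715,0.999996920625,0.331104105819,0,0,0,1
19,0.999733035734,-0.0230922478693,0.000778042422114,25.2977886448,0.0230947840842,0.999727410147,-0.00342583537819,0.0599697710525,-0.000698720095932,0.00344288952431,0.999993829132,0.24832235238,0,0,0,1
20,0.999792188163,-0.0203846066041,0.000219777821163,28.3178408797,0.0203846911064,0.999792134779,-0.000389360776103,-0.0489937981558,-0.00021179517075,0.000393759965321,0.999999900048,0.147087514147,0,0,0,1
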