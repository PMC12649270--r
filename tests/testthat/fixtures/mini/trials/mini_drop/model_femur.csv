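frame_index,m11,m12,m13,m14,m21,m22,m23,m24,m31,m32,m33,m34,m41,m42,m43,m44
1,0.997728116365,-0.0535566942307,-0.0408691364929,-4.51532566439,0.0532985875551,0.998551349563,-0.00737989499673,0.182153723416,0.0412051741803,0.00518486148439,0.99913725325,37.1561173596,0,0,0,1
2,0.994987619187,-0.0923533316034,-0.0383470964488,-4.62424393266,0.0922934827533,0.995726273602,-0.00333183142465,1.10872104371,0.0384909171828,-0.000224056067992,0.999258924951,30.4963563751,0,0,0,1
3,0.997835464763,-0.051663479469,-0.0406850113772,-3.94488805037,0.0516303443556,0.99866452209,-0.00186543827563,-0.333653009755,0.0407270524753,-0.000239180678765,0.999170280778,21.1200538486,0,0,0,1
4,0.997836761456,-0.0559171342363,-0.0345698074419,-3.73002238874,0.0553055962571,0.998299905289,-0.0184008185065,0.521224870646,0.0355399565336,0.0164491093336,0.999232874905,12.2823619365,0,0,0,1
5,0.997497882242,-0.0551655867715,-0.044212362052,-3.6476232357,0.0550522414229,0.998476327589,-0.0037780894113,0.615108129,0.0443534174149,0.00133464655714,0.99901501144,4.66677788832,0,0,0,1
6,0.997817760061,-0.0525670679728,-0.0399552383553,-4.05766863948,0.0522957611575,0.99860113073,-0.00780609178568,-0.174502020404,0.0403096895577,0.0056995674184,0.999170978291,-3.88786238134,0,0,0,1
7,0.997968379545,-0.0495357231324,-0.0400665142259,-3.80096320208,0.0493324744054,0.998764111087,-0.00604626942848,0.0469475199231,0.0403165027936,0.00405740541627,0.999178721283,-12.4322656018,0,0,0,1
8,0.998069263671,-0.0434037857628,-0.0444281025548,-3.51204997995,0.0434120404113,0.999056948911,-0.000779474377939,0.174351784604,0.0444200367232,-0.00115074516507,0.999012280266,-20.6408297856,0,0,0,1
9,0.997948996965,-0.0510128215351,-0.0386715851208,-3.99380313611,0.0508416904469,0.998692145052,-0.00539647335122,-0.537642810393,0.0388962976288,0.0034192764082,0.999237402512,-28.3213736854,0,0,0,1
10,0.997547718695,-0.0441097682625,-0.0543403834149,-3.98335605517,0.0435573407331,0.998986914952,-0.0113093687689,0.449398866504,0.0547841856206,0.00891471241935,0.998458422223,-37.0854540746,0,0,0,1
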