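frame,FE,AA,IE,ML,AP,IS,speed,method,specimen,trial,motion
1,55.02440825,0.19444742195,-0.4012500914,-0.9003829572,-3.196057664,-41.10287467,2.143003864,marker,specimen2,mini_drop,drop
2,54.99185235,0.19155959824,-0.3964604837,-0.8818946652,-3.228266636,-41.09644347,2.167768161,marker,specimen2,mini_drop,drop
3,54.96309741,0.18338278971,-0.3934730977,-0.8666457324,-3.255168628,-41.08993705,2.201527909,marker,specimen2,mini_drop,drop
4,54.93871141,0.17005822720,-0.3915731212,-0.8552194836,-3.275025080,-41.08344072,2.203507524,marker,specimen2,mini_drop,drop
5,54.91852747,0.15181066582,-0.3903030225,-0.8469687753,-3.285839895,-41.07663966,2.172689413,marker,specimen2,mini_drop,drop
6,54.90217518,0.12837041037,-0.3895242854,-0.8408474944,-3.286570231,-41.06927073,2.107028484,marker,specimen2,mini_drop,drop
7,54.88915874,0.09919699796,-0.3892547674,-0.8360947004,-3.277939845,-41.06120539,2.003714936,marker,specimen2,mini_drop,drop
8,54.87857052,0.06438780696,-0.3893649770,-0.8322065320,-3.262362448,-41.05241318,1.859831645,marker,specimen2,mini_drop,drop
9,54.86921138,0.02551886938,-0.3895364835,-0.8287598434,-3.242917970,-41.04301928,1.673437743,marker,specimen2,mini_drop,drop
10,54.86061095,-0.01431337568,-0.3896083075,-0.8255562062,-3.222133820,-41.03351842,1.569472233,marker,specimen2,mini_drop,drop
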