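frame_index,m11,m12,m13,m14,m21,m22,m23,m24,m31,m32,m33,m34,m41,m42,m43,m44
1,0.999770897487,0.0206230381729,-0.00573086675921,-2.63949220214,-0.015792926776,0.530010546341,-0.84784397399,-2.94804826196,-0.0144476988182,0.847740237964,0.530214817725,-3.59992882665,0,0,0,1
2,0.999773562966,0.0205018627134,-0.00570056311628,-2.61907416063,-0.0157029730203,0.530011503753,-0.847845046296,-2.94786856802,-0.0143610387119,0.847742578567,0.530213429717,-11.9216082802,0,0,0,1
3,0.999772316856,0.0205586005558,-0.00571475217323,-2.59381709591,-0.0157450919529,0.530011056823,-0.847844544551,-2.94795274866,-0.014401615486,0.847741483938,0.530214079295,-20.2434763425,0,0,0,1
4,0.99976713016,0.0207931077779,-0.00577339764019,-2.56378486569,-0.0159191768702,0.530009184222,-0.847842464405,-2.94829988293,-0.0145693259676,0.847736935204,0.530216770228,-28.5655321782,0,0,0,1
5,0.999757883399,0.0212047894978,-0.00587634952156,-2.52905356466,-0.0162247867263,0.530005798045,-0.847838787939,-2.94890617243,-0.0148637437086,0.847728854612,0.53022151803,-36.8877723427,0,0,0,1
6,0.999744368251,0.021792601285,-0.00602334448434,-2.48971132622,-0.0166611471733,0.530000744972,-0.847833483948,-2.9497649802,-0.0152841200078,0.847717106621,0.530228349692,-45.210190819,0,0,0,1
7,0.999726290426,0.0225550516403,-0.00621400650554,-2.44585808945,-0.0172271523906,0.529993808291,-0.847826508428,-2.9508668988,-0.015829385707,0.847701499833,0.530237303223,-53.5327790829,0,0,0,1
8,0.999703273728,0.023490205547,-0.00644784779847,-2.39760533202,-0.0179213677025,0.529984710765,-0.847817805272,-2.9521998467,-0.0164981537617,0.847681789706,0.530248426988,-61.8555261939,0,0,0,1
9,0.999674865279,0.0245956890901,-0.00672427001725,-2.34507577021,-0.0187420329857,0.529973118311,-0.847807307156,-2.95374919222,-0.0172887225857,0.847657682054,0.530261778865,-70.178418914,0,0,0,1
10,0.999640541835,0.0258686951448,-0.00704256573905,-2.28840302711,-0.0196870668642,0.52995864446,-0.847794936621,-2.95549790368,-0.0181990801682,0.847628837271,0.530277425229,-78.5014418496,0,0,0,1
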