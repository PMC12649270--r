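frame_index,m11,m12,m13,m14,m21,m22,m23,m24,m31,m32,m33,m34,m41,m42,m43,m44
1,0.997732187762,-0.0522226414682,-0.0424650117415,-4.15477126078,0.0520197848506,0.998628809246,-0.00586884376245,0,0.0427132706337,0.00364651355227,0.999080717185,37.4481354847,0,0,0,1
2,0.997723797234,-0.0523127929773,-0.0425511001379,-4.13817712998,0.0521094945385,0.998624103454,-0.00587371942008,0,0.0427998248942,0.00364303332345,0.999077025708,29.1263275992,0,0,0,1
3,0.997727727858,-0.0522705815597,-0.0425107911897,-4.1111296046,0.0520674900092,0.998626307849,-0.00587143553445,0,0.0427592977995,0.0036446638395,0.999078755093,20.8045197137,0,0,0,1
4,0.997743937622,-0.052096112353,-0.0423441851595,-4.07369700904,0.0518938756287,0.998635400167,-0.00586201381917,0,0.042591790422,0.00365138487206,0.999085885586,12.4827118282,0,0,0,1
5,0.997772253258,-0.0517898199518,-0.0420516964919,-4.02597390129,0.0515890828051,0.998651288565,-0.00584554384005,0,0.0422977205509,0.00366311299639,0.99909833572,4.16090394275,0,0,0,1
6,0.997812372004,-0.0513524674581,-0.0416340529142,-3.96808083407,0.0511538690575,0.998673812551,-0.00582218212947,0,0.0418778217742,0.00367970246973,0.999115963156,-4.16090394275,0,0,0,1
7,0.997863864689,-0.0507851448127,-0.0410922938553,-3.90016405027,0.0505893163781,0.998702744594,-0.00579215063838,0,0.0413331418639,0.00370094676633,0.999138566154,-12.4827118282,0,0,0,1
8,0.997926180111,-0.0500892664031,-0.0404277681786,-3.82239511359,0.0498968288852,0.99873779241,-0.00575573454146,0,0.0406650404636,0.00372658075367,0.999165885667,-20.8045197137,0,0,0,1
9,0.997998650658,-0.0492665679466,-0.039642131229,-3.73497047512,0.0490781297646,0.998778601902,-0.00571327941669,0,0.0398751860739,0.00375628348808,0.999197608019,-29.1263275992,0,0,0,1
10,0.998080499117,-0.0483191026469,-0.0387373411891,-3.63811097708,0.0481352574952,0.998824760723,-0.0056651878275,0,0.0389655523363,0.00378968160165,0.99923336816,-37.4481354847,0,0,0,1
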