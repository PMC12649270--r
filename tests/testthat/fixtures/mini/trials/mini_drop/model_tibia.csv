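frame_index,m11,m12,m13,m14,m21,m22,m23,m24,m31,m32,m33,m34,m41,m42,m43,m44
1,0.999810985535,0.0174483041976,-0.00857612287546,-3.72691389542,-0.0165817337931,0.534966502108,-0.844710534874,-2.69855786075,-0.0101508279151,0.844693079351,0.535154708836,-3.43111622841,0,0,0,1
2,0.999855609589,0.0168815804772,-0.00194221872332,-2.29931246207,-0.0106222824748,0.531700835475,-0.846865626101,-2.54578639335,-0.0132637509026,0.846763977621,0.531803383889,-12.1255595378,0,0,0,1
3,0.999874410093,0.0158473078232,-0.000163937809999,-2.63410604373,-0.00863664945991,0.536191561309,-0.844052141676,-2.73375216686,-0.0132880520377,0.843947553119,0.536261088703,-19.5710222153,0,0,0,1
4,0.999660668288,0.0244708326594,-0.00892897680207,-3.31052919948,-0.020557054206,0.530583084246,-0.847383619286,-3.307619386,-0.0159986186951,0.847279628612,0.530906088813,-28.6008953408,0,0,0,1
5,0.999692702071,0.0240586623467,-0.0059734572795,-2.61426843838,-0.0178389710974,0.530887863771,-0.847254299022,-2.57802574578,-0.0172125691275,0.847100499862,0.531153904813,-36.9839670375,0,0,0,1
6,0.999816840431,0.018546158609,-0.00472499652891,-2.0242656692,-0.0138764502558,0.532451060809,-0.846347039914,-2.55839268924,-0.0131806570264,0.846257589534,0.532610892149,-44.8718186228,0,0,0,1
7,0.999619259475,0.0275850667347,-0.000632598395147,-2.82557582341,-0.0154355417007,0.540050860156,-0.84149082734,-2.65813763634,-0.0228709453214,0.841180202179,0.540271031356,-53.7466974,0,0,0,1
8,0.999762372549,0.0198578564917,0.00899243962965,-1.66220271657,-0.00267370842175,0.521104510079,-0.853488688184,-3.70580446769,-0.0216344567348,0.853261832681,0.521033775461,-61.7713272824,0,0,0,1
9,0.999683793451,0.0245168851267,-0.00558886885894,-2.58658609744,-0.0177234435623,0.52931408518,-0.848240814143,-3.25419416309,-0.0178379555929,0.848071648845,0.529581236229,-69.8629403581,0,0,0,1
10,0.999596559109,0.0277202611104,-0.00618919551392,-2.98365026425,-0.019930959192,0.52933791797,-0.848176942309,-3.46914752064,-0.0202355104413,0.847958109651,0.529676852802,-78.2880777955,0,0,0,1
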