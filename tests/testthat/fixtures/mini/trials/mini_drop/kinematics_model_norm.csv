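frame,FE,AA,IE,ML,AP,IS,speed,method,specimen,trial,motion
1,54.49337734,-0.19052724079,-0.2811005252,-1.484286994,-3.301498319,-40.58546847,2.149910483,model,specimen2,mini_drop,drop
2,54.52402214,-0.12098237477,-0.3538537236,-1.405862868,-3.349201958,-40.73639584,2.173961623,model,specimen2,mini_drop,drop
3,54.55731056,-0.03821075230,-0.4292476262,-1.346710711,-3.413873288,-40.87471365,2.206309534,model,specimen2,mini_drop,drop
4,54.59032718,0.06084659921,-0.5074269122,-1.314631701,-3.495320223,-40.99409089,2.206870701,model,specimen2,mini_drop,drop
5,54.62076993,0.17533608414,-0.5903888296,-1.313869441,-3.594866469,-41.09250560,2.174579277,model,specimen2,mini_drop,drop
6,54.64600811,0.30179024879,-0.6805362594,-1.348076741,-3.715981815,-41.16962618,2.107429215,model,specimen2,mini_drop,drop
7,54.66320240,0.43440033133,-0.7800965573,-1.419388550,-3.861647505,-41.22651585,2.002754276,model,specimen2,mini_drop,drop
8,54.66953812,0.56624900389,-0.8897705105,-1.525617706,-4.030203161,-41.26519567,1.857835288,model,specimen2,mini_drop,drop
9,54.66374988,0.69137805868,-1.0068550282,-1.658844355,-4.214161775,-41.28812850,1.670870006,model,specimen2,mini_drop,drop
10,54.64853972,0.80509006724,-1.1241437619,-1.805002253,-4.400724807,-41.29862103,1.566745134,model,specimen2,mini_drop,drop
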