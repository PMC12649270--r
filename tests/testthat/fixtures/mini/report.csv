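analysis,level,dof,n,mad,mad_sd,bias,loa,loa_ci,outlier_frac
pooled,all,FE,30,0.5135885708,0.6818091286,-0.19566195050,1.6376604194,0.5178736959,0.03333333333
pooled,all,AA,30,0.4302266937,0.4888947102,-0.10961611771,1.2672966608,0.4007543919,0.06666666667
pooled,all,IE,30,0.3649856815,0.2769209963,-0.16322080203,0.8474222793,0.2679784542,0.06666666667
pooled,all,ML,30,0.6160107969,0.3844128190,-0.21743026775,1.3739887148,0.4344933818,0.06666666667
pooled,all,AP,30,0.7332047903,1.0354251040,-0.35019890705,2.4015909325,0.7594497355,0.03333333333
pooled,all,IS,30,0.6391385485,0.4361216035,0.16581940944,1.4982684876,0.4737940967,0.03333333333
bone,femur,FE,30,0.3239067976,0.5684710496,0.14175611248,1.2563967046,NA,0.03333333333
bone,femur,AA,30,0.2019574961,0.2477504467,-0.01087946124,0.6304108130,NA,0.10000000000
bone,femur,IE,30,0.2912703410,0.4589593225,0.12284666718,1.0422996210,NA,0.06666666667
bone,femur,ML,30,0.4146448629,0.3643683112,0.06250508235,1.0852484004,NA,0.06666666667
bone,femur,AP,30,0.4927346795,0.5539546086,0.20020187376,1.4086964215,NA,0.03333333333
bone,femur,IS,30,0.3995955151,0.3712983322,-0.07031090497,1.0698279382,NA,0.06666666667
bone,tibia,FE,30,0.2581713736,0.2369956968,-0.05377149538,0.6849539703,NA,0.06666666667
bone,tibia,AA,30,0.2240634444,0.2292655624,-0.01328943315,0.6330393829,NA,0.06666666667
bone,tibia,IE,30,0.2077561738,0.1452400294,-0.08348358117,0.4742058858,NA,0.03333333333
bone,tibia,ML,30,0.3769812820,0.2559420349,-0.14048075368,0.8590668409,NA,0.03333333333
bone,tibia,AP,30,0.3947303282,0.3006676290,0.03540384115,0.9805667270,NA,0.06666666667
bone,tibia,IS,30,0.4101459277,0.2399655202,0.08398440940,0.9282772107,NA,0.03333333333
specimen,specimen2,FE,30,0.5135885708,0.6818091286,-0.19566195050,1.6376604194,NA,0.03333333333
specimen,specimen2,AA,30,0.4302266937,0.4888947102,-0.10961611771,1.2672966608,NA,0.06666666667
specimen,specimen2,IE,30,0.3649856815,0.2769209963,-0.16322080203,0.8474222793,NA,0.06666666667
specimen,specimen2,ML,30,0.6160107969,0.3844128190,-0.21743026775,1.3739887148,NA,0.06666666667
specimen,specimen2,AP,30,0.7332047903,1.0354251040,-0.35019890705,2.4015909325,NA,0.03333333333
specimen,specimen2,IS,30,0.6391385485,0.4361216035,0.16581940944,1.4982684876,NA,0.03333333333
motion,hop,FE,20,0.5603468112,0.8108403345,-0.20263310256,1.9050908357,NA,0.05000000000
motion,hop,AA,20,0.3876434849,0.4093611331,-0.11994327798,1.0923536572,NA,0.05000000000
motion,hop,IE,20,0.3490587040,0.2514554045,-0.14199512902,0.8087481764,NA,0.05000000000
motion,hop,ML,20,0.6440280584,0.4260134986,-0.20266716451,1.4860548683,NA,0.10000000000
motion,hop,AP,20,0.7800541923,1.2335838511,-0.37655650757,2.7808397355,NA,0.05000000000
motion,hop,IS,20,0.7219131889,0.3935800183,0.35910453028,1.4768441468,NA,0.10000000000
motion,drop,FE,10,0.4200720901,0.3087768077,-0.18171964639,0.9892065098,NA,0.10000000000
motion,drop,AA,10,0.5153931113,0.6358519309,-0.08896179717,1.6288751326,NA,0.10000000000
motion,drop,IE,10,0.3968396365,0.3345453302,-0.20567214804,0.9599981043,NA,0.00000000000
motion,drop,ML,10,0.5599762739,0.2962849061,-0.24695647423,1.1896986493,NA,0.00000000000
motion,drop,AP,10,0.6395059865,0.4768535778,-0.29748370601,1.4971482985,NA,0.00000000000
motion,drop,IS,10,0.4735892676,0.4900750154,-0.22075083222,1.2930587967,NA,0.10000000000
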