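{"id":"mini_drop","specimen":"specimen2","motion":"drop","seed":77797,"n_frames":10,"speed_mps":2.0804519714,"model_outlier_femur":[false,true,false,false,false,false,false,false,false,false],"model_outlier_tibia":[false,false,false,false,false,false,false,false,false,false],"in_fov_femur":[true,true,true,true,true,true,true,true,true,true],"in_fov_tibia":[true,true,true,true,true,true,true,true,true,true]}
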