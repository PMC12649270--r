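{"id":"mini_hop","specimen":"specimen2","motion":"hop","seed":77796,"n_frames":20,"speed_mps":0.74407193523,"model_outlier_femur":[false,false,false,false,false,true,true,false,false,false,false,false,false,false,false,false,false,true,false,false],"model_outlier_tibia":[false,false,false,false,false,true,false,false,false,false,false,false,false,false,false,false,false,false,false,false],"in_fov_femur":[true,true,true,true,true,true,true,true,true,true,true,true,true,true,true,true,true,true,true,true],"in_fov_tibia":[true,true,true,true,true,true,true,true,true,true,true,true,true,true,true,true,true,true,true,true]}
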