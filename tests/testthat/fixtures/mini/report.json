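[{"analysis":"pooled","level":"all","dof":"FE","n":30,"mad":0.51358857083,"mad_sd":0.68180912865,"bias":-0.1956619505,"loa":1.6376604194,"loa_ci":0.51787369591,"outlier_frac":0.033333333333},{"analysis":"pooled","level":"all","dof":"AA","n":30,"mad":0.43022669369,"mad_sd":0.48889471015,"bias":-0.10961611771,"loa":1.2672966608,"loa_ci":0.40075439192,"outlier_frac":0.066666666667},{"analysis":"pooled","level":"all","dof":"IE","n":30,"mad":0.36498568152,"mad_sd":0.27692099627,"bias":-0.16322080203,"loa":0.84742227928,"loa_ci":0.26797845425,"outlier_frac":0.066666666667},{"analysis":"pooled","level":"all","dof":"ML","n":30,"mad":0.61601079692,"mad_sd":0.38441281896,"bias":-0.21743026775,"loa":1.3739887148,"loa_ci":0.43449338183,"outlier_frac":0.066666666667},{"analysis":"pooled","level":"all","dof":"AP","n":30,"mad":0.73320479035,"mad_sd":1.035425104,"bias":-0.35019890705,"loa":2.4015909325,"loa_ci":0.75944973547,"outlier_frac":0.033333333333},{"analysis":"pooled","level":"all","dof":"IS","n":30,"mad":0.63913854847,"mad_sd":0.43612160346,"bias":0.16581940944,"loa":1.4982684876,"loa_ci":0.47379409673,"outlier_frac":0.033333333333},{"analysis":"bone","level":"femur","dof":"FE","n":30,"mad":0.32390679761,"mad_sd":0.56847104964,"bias":0.14175611248,"loa":1.2563967046,"loa_ci":null,"outlier_frac":0.033333333333},{"analysis":"bone","level":"femur","dof":"AA","n":30,"mad":0.20195749609,"mad_sd":0.24775044666,"bias":-0.010879461241,"loa":0.63041081297,"loa_ci":null,"outlier_frac":0.1},{"analysis":"bone","level":"femur","dof":"IE","n":30,"mad":0.29127034096,"mad_sd":0.45895932245,"bias":0.12284666718,"loa":1.042299621,"loa_ci":null,"outlier_frac":0.066666666667},{"analysis":"bone","level":"femur","dof":"ML","n":30,"mad":0.41464486292,"mad_sd":0.36436831118,"bias":0.062505082351,"loa":1.0852484004,"loa_ci":null,"outlier_frac":0.066666666667},{"analysis":"bone","level":"femur","dof":"AP","n":30,"mad":0.49273467949,"mad_sd":0.55395460858,"bias":0.20020187376,"loa":1.4086964215,"loa_ci":null,"outlier_frac":0.033333333333},{"analysis":"bone","level":"femur","dof":"IS","n":30,"mad":0.39959551507,"mad_sd":0.37129833219,"bias":-0.070310904968,"loa":1.0698279382,"loa_ci":null,"outlier_frac":0.066666666667},{"analysis":"bone","level":"tibia","dof":"FE","n":30,"mad":0.25817137356,"mad_sd":0.23699569677,"bias":-0.053771495377,"loa":0.68495397028,"loa_ci":null,"outlier_frac":0.066666666667},{"analysis":"bone","level":"tibia","dof":"AA","n":30,"mad":0.2240634444,"mad_sd":0.22926556241,"bias":-0.01328943315,"loa":0.6330393829,"loa_ci":null,"outlier_frac":0.066666666667},{"analysis":"bone","level":"tibia","dof":"IE","n":30,"mad":0.20775617379,"mad_sd":0.14524002943,"bias":-0.083483581173,"loa":0.47420588582,"loa_ci":null,"outlier_frac":0.033333333333},{"analysis":"bone","level":"tibia","dof":"ML","n":30,"mad":0.37698128201,"mad_sd":0.2559420349,"bias":-0.14048075368,"loa":0.85906684091,"loa_ci":null,"outlier_frac":0.033333333333},{"analysis":"bone","level":"tibia","dof":"AP","n":30,"mad":0.39473032816,"mad_sd":0.30066762902,"bias":0.035403841154,"loa":0.980566727,"loa_ci":null,"outlier_frac":0.066666666667},{"analysis":"bone","level":"tibia","dof":"IS","n":30,"mad":0.41014592766,"mad_sd":0.2399655202,"bias":0.083984409404,"loa":0.92827721067,"loa_ci":null,"outlier_frac":0.033333333333},{"analysis":"specimen","level":"specimen2","dof":"FE","n":30,"mad":0.51358857083,"mad_sd":0.68180912865,"bias":-0.1956619505,"loa":1.6376604194,"loa_ci":null,"outlier_frac":0.033333333333},{"analysis":"specimen","level":"specimen2","dof":"AA","n":30,"mad":0.43022669369,"mad_sd":0.48889471015,"bias":-0.10961611771,"loa":1.2672966608,"loa_ci":null,"outlier_frac":0.066666666667},{"analysis":"specimen","level":"specimen2","dof":"IE","n":30,"mad":0.36498568152,"mad_sd":0.27692099627,"bias":-0.16322080203,"loa":0.84742227928,"loa_ci":null,"outlier_frac":0.066666666667},{"analysis":"specimen","level":"specimen2","dof":"ML","n":30,"mad":0.61601079692,"mad_sd":0.38441281896,"bias":-0.21743026775,"loa":1.3739887148,"loa_ci":null,"outlier_frac":0.066666666667},{"analysis":"specimen","level":"specimen2","dof":"AP","n":30,"mad":0.73320479035,"mad_sd":1.035425104,"bias":-0.35019890705,"loa":2.4015909325,"loa_ci":null,"outlier_frac":0.033333333333},{"analysis":"specimen","level":"specimen2","dof":"IS","n":30,"mad":0.63913854847,"mad_sd":0.43612160346,"bias":0.16581940944,"loa":1.4982684876,"loa_ci":null,"outlier_frac":0.033333333333},{"analysis":"motion","level":"hop","dof":"FE","n":20,"mad":0.5603468112,"mad_sd":0.81084033453,"bias":-0.20263310256,"loa":1.9050908357,"loa_ci":null,"outlier_frac":0.05},{"analysis":"motion","level":"hop","dof":"AA","n":20,"mad":0.38764348488,"mad_sd":0.40936113306,"bias":-0.11994327798,"loa":1.0923536572,"loa_ci":null,"outlier_frac":0.05},{"analysis":"motion","level":"hop","dof":"IE","n":20,"mad":0.34905870404,"mad_sd":0.2514554045,"bias":-0.14199512902,"loa":0.80874817638,"loa_ci":null,"outlier_frac":0.05},{"analysis":"motion","level":"hop","dof":"ML","n":20,"mad":0.64402805841,"mad_sd":0.42601349864,"bias":-0.20266716451,"loa":1.4860548683,"loa_ci":null,"outlier_frac":0.1},{"analysis":"motion","level":"hop","dof":"AP","n":20,"mad":0.78005419226,"mad_sd":1.2335838511,"bias":-0.37655650757,"loa":2.7808397355,"loa_ci":null,"outlier_frac":0.05},{"analysis":"motion","level":"hop","dof":"IS","n":20,"mad":0.72191318889,"mad_sd":0.39358001825,"bias":0.35910453028,"loa":1.4768441468,"loa_ci":null,"outlier_frac":0.1},{"analysis":"motion","level":"drop","dof":"FE","n":10,"mad":0.42007209011,"mad_sd":0.30877680772,"bias":-0.18171964639,"loa":0.98920650978,"loa_ci":null,"outlier_frac":0.1},{"analysis":"motion","level":"drop","dof":"AA","n":10,"mad":0.51539311131,"mad_sd":0.63585193092,"bias":-0.08896179717,"loa":1.6288751326,"loa_ci":null,"outlier_frac":0.1},{"analysis":"motion","level":"drop","dof":"IE","n":10,"mad":0.39683963648,"mad_sd":0.33454533023,"bias":-0.20567214804,"loa":0.95999810432,"loa_ci":null,"outlier_frac":0},{"analysis":"motion","level":"drop","dof":"ML","n":10,"mad":0.55997627393,"mad_sd":0.29628490607,"bias":-0.24695647423,"loa":1.1896986493,"loa_ci":null,"outlier_frac":0},{"analysis":"motion","level":"drop","dof":"AP","n":10,"mad":0.63950598652,"mad_sd":0.47685357779,"bias":-0.29748370601,"loa":1.4971482985,"loa_ci":null,"outlier_frac":0},{"analysis":"motion","level":"drop","dof":"IS","n":10,"mad":0.47358926763,"mad_sd":0.49007501542,"bias":-0.22075083222,"loa":1.2930587967,"loa_ci":null,"outlier_frac":0.1}]
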