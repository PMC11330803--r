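{"config":{"hidden_channels":3,"cell_layers":2,"sequence_length":3,"input_dim":[12,12],"k":3,"pool_channels":2,"fc_dim":8},"seed":77,"input":[0.717278,0.258146,1.075058,-0.537578,-1.326442,1.181735,-0.351241,-0.558665,-0.752996,-1.752317,-1.094336,-0.411022,0.015331,1.410507,-0.332203,-1.563374,0.462956,-1.35193,-2.501334,-0.688247,-1.662107,0.254156,-1.765641,0.370603,-0.505075,0.649583,1.548414,0.143122,-0.193265,-0.233732,1.001177,-1.144146,-0.801866,0.886039,1.001623,-0.038391,-0.436451,0.728105,0.994871,-0.112808,-1.131894,0.060925,0.056591,-0.224059,-0.53057,-0.697362,-0.74271,0.771146,0.418931,2.053443,-0.246436,-1.312332,0.844945,0.60025,1.708118,2.084995,-3.126847,-0.06077,0.960131,-0.581102,-1.150906,0.828677,0.535619,0.839128,-1.999827,-0.751514,1.326802,-0.976512,-0.82166,-0.561437,0.571276,-0.087425,-1.686549,0.5772,-0.9897,0.416937,-0.364203,-1.560758,-0.055591,-0.191144,1.675692,0.606762,-1.014913,-2.051932,0.968779,-0.536258,0.709043,0.258584,0.374368,2.065454,0.732908,0.049445,1.330435,1.5799,0.041211,-1.237947,-0.599638,0.08689,-0.2365,0.105579,-0.494834,1.61479,1.277593,-0.336449,0.360791,0.088657,-2.874344,-0.016824,-0.386476,1.001022,-1.556907,1.283664,0.521805,-0.462293,-0.584774,0.831836,-1.564961,-1.364132,1.695411,3.093347,-1.486871,0.384579,-0.946699,1.254898,-0.50186,-1.44472,-0.336189,0.491604,0.438052,-0.442245,1.459393,-0.900821,0.620565,0.232522,0.223286,0.247141,0.352723,0.02764,-1.030038,0.10532,0.794022,1.11462,-1.435581,0.434424,-0.161838,-0.090217,-0.91907,1.008828,0.097919,1.110604,-0.55571,-0.008242,-0.016671,-1.31997,-2.342078,0.130259,0.468076,-2.128773,0.603035,-1.038362,1.024581,0.068534,0.346444,-0.352918,1.147978,1.708917,-0.659235,-2.504042,-0.540885,-1.375713,-0.709855,-0.884698,0.329566,-0.53303,1.707937,-0.489563,-2.138096,-0.061761,0.611737,-0.048765,-0.125451,1.064863,0.859776,0.080007,0.806767,0.628816,0.532527,-0.786432,1.447585,1.217176,1.257197,0.836527,0.225915,1.222787,-0.610643,1.890766,-0.243173,-2.261848,-1.421604,0.455296,0.794957,0.762844,0.246874,-0.885066,-0.791445,0.353043,0.282967,1.544378,-0.172164,-0.569732,-1.183832,0.114395,0.967622,0.729765,-0.289828,0.83274,0.901605,-1.124796,0.242327,0.271658,0.874044,-0.787589,-0.791059,0.724114,0.223047,-1.074327,0.31548,0.050066,0.19145,0.441819,0.472192,0.564881,-0.610686,-0.859959,1.701697,0.111563,1.231445,-0.425806,1.110135,0.334788,-1.078294,0.776769,-0.984218,-1.816715,1.363373,0.70408,-1.473752,-0.853437,-1.005659,1.072524,-0.82492,-0.673555,-1.784535,-0.6145,2.889156,0.729279,0.750796,0.787667,0.931026,0.142906,-0.007358,-0.965362,-0.42974,0.567703,0.184755,-1.677293,0.797625,0.885439,0.811197,1.774591,0.859437,1.179959,-1.090564,-3.155624,2.410831,0.947948,-0.68019,1.124301,-0.331253,0.408366,1.653684,0.547071,-0.114477,0.180377,-0.753265,0.693926,-1.110038,-1.086468,-0.520811,-1.061248,1.348707,0.708344,0.732261,1.253775,1.071166,-0.02153,0.035465,-0.53482,-2.082824,0.059006,-0.65422,-0.538508,-1.178838,-0.407513,0.494714,-0.32121,-0.184902,-0.682352,-0.674021,-1.032642,1.752137,-1.974882,0.11759,-1.103718,-1.590135,0.895508,-0.131281,-1.787897,-0.701194,1.251236,1.812977,-0.970471,-0.275287,-0.15608,-0.997369,0.558933,-0.481662,-1.918488,-0.353519,0.719708,0.036532,-0.520033,0.589445,0.674029,-0.257083,-1.452734,0.117174,0.729739,0.596438,-0.124277,-0.032721,0.544618,1.002254,-1.128683,-0.714675,-0.621168,-0.459436,1.269313,0.638521,2.253501,0.694027,1.32386,0.238654,-0.371924,-0.613227,-0.443032,1.037181,0.963551,-1.177923,-0.163565,1.357114,-0.060136,-0.895003,-0.396769,-2.30961,0.945228,-1.512368,0.476275,0.760629,-0.237497,-0.551458,0.051214,0.954084,0.878379,0.301325,1.359945,0.471507,0.424219,0.387237,-0.687316,1.330674,0.4508,1.204135,-0.565658,0.083474,-0.303681,-0.829408,1.835381,0.628834,0.739963,0.60569,-1.641061,-0.682452,-0.678431,2.111159,0.580754,-0.165998,-0.405607,2.432276,0.736113,-1.342789,-0.494251,-0.361337,-0.991026,0.726737,2.421017,0.12901,0.243609,-1.230218,-1.000164,0.441431,-1.206435,-0.455544,-1.609142,0.164398,-0.580232,1.707595,-0.789439,0.543507,-1.631347,-0.009969,-0.920994,0.916167,-0.802476,-1.767058,-1.015786,-0.917927,0.085699,-0.591353,-0.09769,0.53983,0.23106],"input_dim":[12,12,3,1],"output":[-0.0669697337528706,-0.0158560353832228,0.174013448214971]}
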