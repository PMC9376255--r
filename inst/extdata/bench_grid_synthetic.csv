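p_aorta_mmHg,p_act_psi,g_exp,t_on_s,t_off_s
50,6,0.2687354618925767,0.288,0.476
50,7,0.3068364332422208,0.292,0.484
50,8,0.32664371387589947,0.296,0.492
50,9,0.38095280802137793,0.3,0.5
50,10,0.39829507771815365,0.304,0.508
50,11,0.41679531615881976,0.308,0.516
50,12,0.4598742905242848,0.312,0.524
60,6,0.25618324705129214,0.288,0.476
60,7,0.28415781351653496,0.292,0.484
60,8,0.3049461161284365,0.296,0.492
60,9,0.35271781168450855,0.3,0.5
60,10,0.3710984323641143,0.304,0.508
60,11,0.390587594194582,0.308,0.516
60,12,0.40425300112822504,0.312,0.524
70,6,0.23424930918143108,0.288,0.476
70,7,0.25175066390984774,0.292,0.484
70,8,0.2812380973690105,0.296,0.492
70,9,0.32003836210685305,0.3,0.5
70,10,0.34801221195098087,0.304,0.508
70,11,0.3749390132121751,0.308,0.516
70,12,0.4073897737160822,0.312,0.524
80,6,0.2054213630073107,0.288,0.476
80,7,0.22714564983365193,0.292,0.484
80,8,0.2353064830413663,0.296,0.492
80,9,0.2901982574789472,0.3,0.5
80,10,0.31223871260471,0.304,0.508
80,11,0.3400420449329467,0.308,0.516
80,12,0.3556924761610073,0.312,0.524
90,6,0.1678184994489138,0.288,0.476
90,7,0.20517941560199704,0.292,0.484
90,8,0.24298679551529043,0.296,0.492
90,9,0.2567721227265701,0.3,0.5
90,10,0.2900767161155937,0.304,0.508
90,11,0.3140619495941709,0.308,0.516
90,12,0.3292294044317139,0.312,0.524
100,6,0.14385005436700318,0.288,0.476
100,7,0.1720571004628965,0.292,0.484
100,8,0.20340686603288813,0.296,0.492
100,9,0.24300025371983885,0.3,0.5
100,10,0.26763175748457546,0.304,0.508
100,11,0.2863547640374641,0.308,0.516
100,12,0.3134663831986349,0.312,0.524
125,6,0.09521963375404736,0.288,0.476
125,7,0.12081663198673656,0.292,0.484
125,8,0.1353624430545048,0.296,0.492
125,9,0.1621750484303788,0.3,0.5
125,10,0.1998958196213683,0.304,0.508
125,11,0.23093532924515417,0.308,0.516
125,12,0.24912653787849776,0.312,0.524
150,6,0.03981107726454217,0.288,0.476
150,7,0.06098105880367071,0.292,0.484
150,8,0.07687973606749232,0.296,0.492
150,9,0.11241119691424431,0.3,0.5
150,10,0.1237063690391921,0.304,0.508
150,11,0.17533023701701037,0.308,0.516
150,12,0.2068039989850586,0.312,0.524
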