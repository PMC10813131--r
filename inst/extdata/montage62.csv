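"name","x","y","z"
"FPZ",0,0.92,0.391918358845308
"FP1",-0.12,0.92,0.373095162123553
"FP2",0.12,0.92,0.373095162123553
"AF3",-0.225,0.75,0.621992765231236
"AF4",0.225,0.75,0.621992765231236
"AF7",-0.435,0.75,0.498272014064607
"AF8",0.435,0.75,0.498272014064607
"FZ",0,0.55,0.835164654424503
"F1",-0.12,0.55,0.826498638837355
"F2",0.12,0.55,0.826498638837355
"F3",-0.225,0.55,0.804285397107271
"F4",0.225,0.55,0.804285397107271
"F5",-0.33,0.55,0.767202711152665
"F6",0.33,0.55,0.767202711152665
"F7",-0.435,0.55,0.712934078298969
"F8",0.435,0.55,0.712934078298969
"FCZ",0,0.3,0.953939201416946
"FC1",-0.12,0.3,0.946361453145678
"FC2",0.12,0.3,0.946361453145678
"FC3",-0.225,0.3,0.927024810886958
"FC4",0.225,0.3,0.927024810886958
"FC5",-0.33,0.3,0.895041898460625
"FC6",0.33,0.3,0.895041898460625
"FT7",-0.435,0.3,0.848984687729997
"FT8",0.435,0.3,0.848984687729997
"CZ",0,0,1
"C1",-0.12,0,0.992773891679269
"C2",0.12,0,0.992773891679269
"C3",-0.225,0,0.974358763495254
"C4",0.225,0,0.974358763495254
"C5",-0.33,0,0.943980932010811
"C6",0.33,0,0.943980932010811
"T7",-0.435,0,0.900430452616969
"T8",0.435,0,0.900430452616969
"CPZ",0,-0.3,0.953939201416946
"CP1",-0.12,-0.3,0.946361453145678
"CP2",0.12,-0.3,0.946361453145678
"CP3",-0.225,-0.3,0.927024810886958
"CP4",0.225,-0.3,0.927024810886958
"CP5",-0.33,-0.3,0.895041898460625
"CP6",0.33,-0.3,0.895041898460625
"TP7",-0.435,-0.3,0.848984687729997
"TP8",0.435,-0.3,0.848984687729997
"PZ",0,-0.55,0.835164654424503
"P1",-0.12,-0.55,0.826498638837355
"P2",0.12,-0.55,0.826498638837355
"P3",-0.225,-0.55,0.804285397107271
"P4",0.225,-0.55,0.804285397107271
"P5",-0.33,-0.55,0.767202711152665
"P6",0.33,-0.55,0.767202711152665
"P7",-0.435,-0.55,0.712934078298969
"P8",0.435,-0.55,0.712934078298969
"POZ",0,-0.75,0.661437827766148
"PO3",-0.225,-0.75,0.621992765231236
"PO4",0.225,-0.75,0.621992765231236
"PO5",-0.33,-0.75,0.573236425918661
"PO6",0.33,-0.75,0.573236425918661
"PO7",-0.435,-0.75,0.498272014064607
"PO8",0.435,-0.75,0.498272014064607
"OZ",0,-0.92,0.391918358845308
"O1",-0.12,-0.92,0.373095162123553
"O2",0.12,-0.92,0.373095162123553
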