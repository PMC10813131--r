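"channel","region"
"FP1","LF"
"FP2","RF"
"AF3","LF"
"AF4","RF"
"AF7","LF"
"AF8","RF"
"F1","LF"
"F2","RF"
"F3","LF"
"F4","RF"
"F5","LF"
"F6","RF"
"F7","LF"
"F8","RF"
"FC1","LC"
"FC2","RC"
"FC3","LC"
"FC4","RC"
"FC5","LC"
"FC6","RC"
"FT7","LT"
"FT8","RT"
"C1","LC"
"C2","RC"
"C3","LC"
"C4","RC"
"C5","LC"
"C6","RC"
"T7","LT"
"T8","RT"
"CP1","LC"
"CP2","RC"
"CP3","LC"
"CP4","RC"
"CP5","LC"
"CP6","RC"
"TP7","LT"
"TP8","RT"
"P1","LP"
"P2","RP"
"P3","LP"
"P4","RP"
"P5","LP"
"P6","RP"
"P7","LP"
"P8","RP"
"PO3","LO"
"PO4","RO"
"PO5","LO"
"PO6","RO"
"PO7","LO"
"PO8","RO"
"O1","LO"
"O2","RO"
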