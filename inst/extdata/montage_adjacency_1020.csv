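"channel","neighbor"
"C3","Cz"
"C3","F3"
"C3","P3"
"C4","Cz"
"C4","F4"
"C4","P4"
"Cz","C3"
"Cz","C4"
"Cz","Fz"
"Cz","Pz"
"F3","C3"
"F3","Fz"
"F4","C4"
"F4","Fz"
"Fz","Cz"
"Fz","F3"
"Fz","F4"
"O1","O2"
"O1","P3"
"O1","Pz"
"O2","O1"
"O2","P4"
"O2","Pz"
"P3","C3"
"P3","O1"
"P3","Pz"
"P4","C4"
"P4","O2"
"P4","Pz"
"Pz","Cz"
"Pz","O1"
"Pz","O2"
"Pz","P3"
"Pz","P4"
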