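residue_name,atom_name,charge,lj_sigma,lj_epsilon,vdw_radius
M3L,NZ,0.30,3.25,0.17,1.55
M3L,CZ1,0.25,3.40,0.09,1.70
M3L,CZ2,0.25,3.40,0.09,1.70
M3L,CZ3,0.25,3.40,0.09,1.70
M3L,CE,0.10,3.40,0.09,1.70
M3L,CD,0.00,3.40,0.09,1.70
FE2,FE,2.00,2.30,0.01,1.30
HOH,O,-0.40,3.00,0.21,1.52
GLY,O,-0.50,3.00,0.21,1.52
TYR,OH,-0.50,3.00,0.21,1.52
SER,OG,-0.50,3.00,0.21,1.52
ASN,OD1,-0.50,3.00,0.21,1.52
GLU,OE1,-0.80,3.00,0.21,1.52
GLU,OE2,-0.80,3.00,0.21,1.52
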