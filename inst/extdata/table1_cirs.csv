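# CIRS tissue-surrogate calibration phantom (9 inserts).
# Assumed molecular compositions (percent by mass), manufacturer-provided mass
# density rho (g/cc) and electron density rho_e (relative to water), and mean
# CT numbers measured at 120 kVp (hu_kv) and 3.5 MV (hu_mv).
# The rho_e column derives from the manufacturer's undisclosed elemental data
# and is NOT recomputable from the molecular columns; it is carried as data.
name,omega_water,omega_lipid,omega_protein,omega_mineral,rho,rho_e,hu_kv,hu_mv
Adipose,30,55,15,0,0.958,0.947,-63,-50
Breast,50,25,25,0,0.989,0.974,-31,-24
Liquid Water,100,0,0,0,1.000,1.000,0,0
Solid Water,100,0,0,0,1.016,1.000,2,4
Muscle,75,5,20,0,1.067,1.047,49,55
Liver,75,5,20,0,1.069,1.050,54,58
Trab Bone,10,40,30,20,1.164,1.119,247,134
Dense Bone (800),5,20,35,40,1.613,1.515,910,534
Dense Bone (1750),3,2,40,55,2.150,1.968,1865,1008
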