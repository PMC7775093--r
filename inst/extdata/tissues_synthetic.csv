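# SYNTHETIC reference-tissue table for the beta regression.
# Each row is a representative human tissue expressed as a mass-fraction
# mixture of the bundled molecule library (water / lipid / protein /
# mineral); elemental compositions are derived from the molecule library at
# load time.  The rows span the molecular simplex from lipid-heavy marrow to
# mineral-heavy cortical bone.  This table is constructed, not transcribed
# from any tissue compilation.
name,omega_water,omega_lipid,omega_protein,omega_mineral
Yellow Marrow,0.15,0.80,0.05,0.00
Adipose,0.21,0.74,0.05,0.00
Breast,0.51,0.33,0.16,0.00
Whole Blood,0.80,0.01,0.19,0.00
Urine,0.95,0.00,0.05,0.00
Skin,0.65,0.05,0.30,0.00
Muscle,0.75,0.05,0.20,0.00
Liver,0.71,0.07,0.22,0.00
Brain,0.77,0.11,0.12,0.00
Cartilage,0.65,0.00,0.25,0.10
Spongiosa,0.27,0.47,0.13,0.13
Trabecular Bone,0.27,0.35,0.23,0.15
Cortical Bone,0.10,0.00,0.30,0.60
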