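# Representative elemental mass fractions for the empirically characterized
# molecule classes of the four-component tissue model.
# lipid: triolein-like triglyceride (C57H104O6), a literature-style stand-in
#   for dietary/depot fats such as coconut oil.
# protein: gelatin-like structural protein (CHNOS).
# Water and hydroxyapatite are built stoichiometrically in code and are not
# listed here.
molecule,element,mass_fraction
lipid,H,0.118
lipid,C,0.773
lipid,O,0.109
protein,H,0.070
protein,C,0.532
protein,N,0.161
protein,O,0.226
protein,S,0.011
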