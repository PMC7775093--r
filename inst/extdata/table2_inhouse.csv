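# In-house tissue-mimicking phantom (distilled water / coconut oil /
# porcine gelatin / hydroxyapatite mixtures).
# Molecular compositions in percent by mass; ground-truth rho (g/cc, from
# mass/volume measurement) and rho_e (from measured elemental composition)
# with their standard uncertainties; and rho / rho_e as determined by imaging:
# *_kv1 / *_mv1 = clinical piecewise-linear interpolation baseline,
# *_kv5 / *_mv5 = molecular-composition method.
name,omega_water,omega_lipid,omega_protein,omega_mineral,rho_truth,rho_truth_sd,rho_e_truth,rho_e_truth_sd,rho_kv1,rho_e_kv1,rho_kv5,rho_e_kv5,rho_mv1,rho_e_mv1,rho_mv5,rho_e_mv5
Skin,75,0,25,0,1.060,0.002,1.048,0.002,1.052,1.033,1.053,1.042,1.065,1.045,1.068,1.057
Muscle,75,5,20,0,1.045,0.002,1.036,0.002,1.034,1.017,1.035,1.027,1.051,1.032,1.051,1.042
Adipose,47,49,4,0,0.953,0.002,0.955,0.002,0.941,0.931,0.946,0.947,0.970,0.958,0.960,0.961
Spongiosa,27,47,13,13,1.060,0.002,1.044,0.002,1.099,1.071,1.065,1.046,1.055,1.036,1.059,1.041
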