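# Reference coefficient values as printed for the bundled beam pair; used as
# expected values throughout the suite.
alpha_kv_printed <- c(lipid = -50.8, protein = -58.1, mineral = 604.8)
alpha_mv_printed <- c(lipid = 4.5, protein = -54.7, mineral = -77.5)
beta_printed <- c(lipid = 0.00499, protein = -0.0419, mineral = -0.113)

params_kv_printed <- model_params(alpha_kv_printed, beta_printed, beam = "kv")
params_mv_printed <- model_params(alpha_mv_printed, beta_printed, beam = "mv")

# a small synthetic phantom table generated exactly from given params
synthetic_materials <- function(params, n = 6, seed = 7, noise_sd = 0) {
  set.seed(seed)
  om <- sample_tissue_compositions(
    c(water = 0.4, lipid = 0.25, protein = 0.25, mineral = 0.1),
    variation = 0.8, n = n)
  rho <- runif(n, 0.9, 1.8)
  hu <- vapply(seq_len(n), function(i) {
    simulate_hu(rho[i], as_molecular_composition(unlist(om[i, ])), params)
  }, numeric(1))
  if (noise_sd > 0) hu <- hu + rnorm(n, 0, noise_sd)
  calibration_materials(data.frame(
    name = paste0("m", seq_len(n)),
    omega_water = om$water, omega_lipid = om$lipid,
    omega_protein = om$protein, omega_mineral = om$mineral,
    rho = rho, hu_kv = hu))
}
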