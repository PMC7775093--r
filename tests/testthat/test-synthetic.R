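mats2 <- function() {
  calibration_materials(data.frame(
    name = c("watery", "fatty", "bony"),
    omega_water = c(0.9, 0.3, 0.1), omega_lipid = c(0.0, 0.6, 0.1),
    omega_protein = c(0.1, 0.1, 0.3), omega_mineral = c(0.0, 0.0, 0.5),
    rho = c(1.02, 0.95, 1.60), hu_kv = c(NA, NA, NA)))
}

regions3 <- list(
  list(material = "watery", from = c(1, 1, 1), to = c(10, 10, 10)),
  list(material = "fatty", from = c(11, 1, 1), to = c(20, 10, 10)),
  list(material = "bony", from = c(1, 11, 1), to = c(10, 20, 10)))

test_that("noiseless phantoms equal the model prediction voxel for voxel", {
  spec <- phantom_spec(mats2(), regions3, dim = c(20, 20, 10), noise_sd = 0)
  ph <- generate_phantom(spec, params_kv_printed)
  for (i in 1:3) {
    expect_equal(unique(ph$hu[ph$labels == i]), ph$truth$hu_noiseless[i],
                 tolerance = 1e-12)
  }
  expect_true(all(ph$hu[ph$labels == 0] == -1000))
  expect_equal(ph$truth$n_voxels, c(1000, 1000, 1000))
})

test_that("phantom generation is deterministic under a fixed seed", {
  spec <- phantom_spec(mats2(), regions3, dim = c(20, 20, 10),
                       noise_sd = 10, seed = 123)
  p1 <- generate_phantom(spec, params_kv_printed)
  p2 <- generate_phantom(spec, params_kv_printed)
  expect_identical(p1$hu, p2$hu)
})

test_that("noisy ROI means stay within the standard-error bound", {
  spec <- phantom_spec(mats2(), regions3, dim = c(20, 20, 10),
                       noise_sd = 10, seed = 99)
  ph <- generate_phantom(spec, params_kv_printed)
  for (i in 1:3) {
    roi_mean <- mean(ph$hu[ph$labels == i])
    expect_lt(abs(roi_mean - ph$truth$hu_noiseless[i]), 3 * 10 / sqrt(1000))
  }
})

test_that("invalid phantom geometry is refused", {
  expect_error(phantom_spec(mats2(), list(
    list(material = "watery", from = c(1, 1, 1), to = c(25, 10, 10))),
    dim = c(20, 20, 10)), "outside")
  expect_error(phantom_spec(mats2(), list(
    list(material = "watery", from = c(1, 1, 1), to = c(10, 10, 10)),
    list(material = "fatty", from = c(5, 5, 5), to = c(12, 12, 10))),
    dim = c(20, 20, 10)), "overlap")
  expect_error(phantom_spec(mats2(), list(
    list(material = "granite", from = c(1, 1, 1), to = c(2, 2, 2))),
    dim = c(20, 20, 10)), "granite")
})

test_that("phantom-to-calibration loop recovers the generating coefficients", {
  # noiseless: ROI means fed back through the phantom fit give alpha exactly
  mats <- synthetic_materials(params_kv_printed, n = 5, seed = 31)
  regions <- lapply(1:5, function(i) {
    list(material = paste0("m", i), from = c(1, 1, i), to = c(10, 10, i))
  })
  spec <- phantom_spec(mats, regions, dim = c(10, 10, 5), noise_sd = 0)
  ph <- generate_phantom(spec, params_kv_printed)
  roi <- vapply(1:5, function(i) mean(ph$hu[ph$labels == i]), numeric(1))
  mats$hu_kv <- roi
  f0 <- fit_alpha_from_phantom(mats, "kv")
  expect_lt(max(abs(f0$alpha - params_kv_printed$alpha) /
                  abs(params_kv_printed$alpha)), 1e-9)

  # with seeded noise: recovery within three standard errors
  spec_n <- phantom_spec(mats, regions, dim = c(10, 10, 5),
                         noise_sd = 8, seed = 4)
  phn <- generate_phantom(spec_n, params_kv_printed)
  mats$hu_kv <- vapply(1:5, function(i) mean(phn$hu[phn$labels == i]),
                       numeric(1))
  fn <- fit_alpha_from_phantom(mats, "kv")
  expect_true(all(abs(fn$alpha - params_kv_printed$alpha) <= 3 * fn$se))
})

test_that("noiseless phantom conversion recovers ground truth exactly", {
  spec <- phantom_spec(mats2(), regions3, dim = c(20, 20, 10), noise_sd = 0)
  ph <- generate_phantom(spec, params_kv_printed)
  res <- suppressMessages(
    convert_volume(ph$hu, ph$labels, mats2(), params_kv_printed))
  for (i in 1:3) {
    expect_equal(unique(res$rho[ph$labels == i]), mats2()$rho[i],
                 tolerance = 1e-12)
    expect_equal(unique(res$rho_e[ph$labels == i]), ph$truth$rho_e[i],
                 tolerance = 1e-12)
  }
})

test_that("composition sampling respects the simplex and the variation knob", {
  base <- c(water = 0.75, lipid = 0.05, protein = 0.2)
  fixed <- sample_tissue_compositions(base, variation = 0, n = 4, seed = 2)
  expect_equal(unname(as.matrix(fixed)),
               matrix(c(0.75, 0.05, 0.2, 0), 4, 4, byrow = TRUE),
               tolerance = 1e-12)
  draws <- sample_tissue_compositions(base, variation = 0.1, n = 200, seed = 2)
  expect_equal(rowSums(draws), rep(1, 200), tolerance = 1e-12)
  expect_true(all(draws$mineral == 0))  # zero components stay zero
  expect_true(all(draws >= 0))
  expect_error(sample_tissue_compositions(base, variation = 1.2, n = 2),
               "variation")
})

test_that("natural soft-tissue composition variation keeps conversion errors small", {
  # muscle-like tissue, 10% relative composition scatter: converting with the
  # nominal composition should stay within 0.7% on electron density
  base <- c(water = 0.75, lipid = 0.05, protein = 0.2)
  draws <- sample_tissue_compositions(base, variation = 0.1, n = 1000, seed = 17)
  errs <- vapply(seq_len(nrow(draws)), function(i) {
    true <- as_molecular_composition(unlist(draws[i, ]))
    composition_error(as_molecular_composition(base), true,
                      params_kv_printed)$rho_e_error_pct
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.7)
})
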