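tab <- attenuation_table()

test_that("mixture rule reduces to single elements and averages mass fractions", {
  # single element at a grid node returns the tabulated value
  expect_equal(mixture_mu_over_rho(c(O = 1), tab, 60), 0.1907, tolerance = 1e-10)
  # 50/50 by mass at one energy is the arithmetic mean
  expect_equal(mixture_mu_over_rho(c(H = 0.5, O = 0.5), tab, 80),
               mean(c(mixture_mu_over_rho(c(H = 1), tab, 80),
                      mixture_mu_over_rho(c(O = 1), tab, 80))),
               tolerance = 1e-12)
  expect_error(mixture_mu_over_rho(c(O = 1), tab, 5), "outside")
  expect_error(mixture_mu_over_rho(c(O = 1), tab, 5000), "outside")
})

test_that("water mu/rho matches an independent per-element re-summation", {
  # oracle: read the fixture file directly and interpolate by hand
  raw <- read.csv(system.file("extdata", "mass_attenuation_xcomstyle.csv",
                              package = "humol"), comment.char = "#")
  interp <- function(el, E) {
    d <- raw[raw$element == el, ]
    exp(approx(log(d$energy_kev), log(d$mu_over_rho), log(E))$y)
  }
  w <- c(H = 0.1119, O = 0.8881)
  for (E in c(35, 60, 72.5, 500)) {
    expect_equal(mixture_mu_over_rho(w, tab, E),
                 0.1119 * interp("H", E) + 0.8881 * interp("O", E),
                 tolerance = 1e-12)
  }
})

test_that("mixture rule is linear in mass fractions", {
  set.seed(3)
  for (i in 1:10) {
    f <- runif(1)
    a <- c(H = f, Ca = 1 - f)
    expect_equal(mixture_mu_over_rho(a, tab, 100),
                 f * mixture_mu_over_rho(c(H = 1), tab, 100) +
                   (1 - f) * mixture_mu_over_rho(c(Ca = 1), tab, 100),
                 tolerance = 1e-12)
  }
})

test_that("spectrum weighting degenerates correctly and respects normalization", {
  w <- c(H = 0.1119, O = 0.8881)
  mono <- beam_model(70, 1, "mono70")
  expect_equal(spectrum_weighted_mu_over_rho(w, mono, tab),
               mixture_mu_over_rho(w, tab, 70), tolerance = 1e-12)
  two <- beam_model(c(50, 90), c(0.5, 0.5))
  expect_equal(spectrum_weighted_mu_over_rho(w, two, tab),
               mean(mixture_mu_over_rho(w, tab, c(50, 90))), tolerance = 1e-12)
  # weight rescaling leaves the weighted value (and hence alpha) unchanged
  scaled <- beam_model(c(50, 90), c(3.5, 3.5))
  expect_equal(spectrum_weighted_mu_over_rho(w, scaled, tab),
               spectrum_weighted_mu_over_rho(w, two, tab), tolerance = 1e-12)
})

test_that("beam models validate their grids and weights", {
  expect_error(beam_model(c(50, 40), c(1, 1)), "increasing")
  expect_error(beam_model(c(50, 60), c(1, -1)), "non-negative")
  b <- beam_model(c(10, 20, 30), c(1, 2, 1))
  expect_equal(sum(b$weight), 1, tolerance = 1e-12)
  expect_equal(b$mean_energy, 20)
})

test_that("gamma beam model hits its target mean and normalizes", {
  mv <- gamma_spectrum()
  expect_equal(mv$mean_energy, 860, tolerance = 1e-6)
  expect_equal(sum(mv$weight), 1, tolerance = 1e-6)
  # shape 1 on a wide grid: exponential spectrum with mean ~ scale
  b <- gamma_spectrum(shape = 1, scale = 500, grid = seq(1, 6000, by = 1))
  expect_equal(b$mean_energy, 500, tolerance = 0.02)
  # closed-form gamma mean shape*scale up to grid truncation
  b2 <- gamma_spectrum(shape = 2, scale = 300, grid = seq(1, 6000, by = 1))
  expect_equal(b2$mean_energy, 600, tolerance = 0.02)
  expect_error(gamma_spectrum(shape = -1, scale = 100), "positive")
})

test_that("spectrum-route alphas vanish for water and need a water reference", {
  mols <- load_fixture("molecules")
  kv <- load_fixture("spectrum_kv")
  a <- alpha_from_spectrum(list(water = mols$water, lipid = mols$water),
                           kv, tab)
  expect_equal(unname(a["lipid"]), 0, tolerance = 1e-12)
  expect_error(alpha_from_spectrum(list(lipid = mols$lipid), kv, tab),
               "water")
})

test_that("analytic betas follow from Z/A arithmetic", {
  expect_equal(beta_analytic(elemental_from_formula(c(H = 2, O = 1))), 0,
               tolerance = 1e-12)
  # pure carbon, by hand from the constants table
  expect_equal(beta_analytic(c(C = 1)),
               (6 / 12.011) / (10 / 18.015) - 1, tolerance = 1e-4)
})

test_that("simulated CT numbers invert the density normalization exactly", {
  expect_equal(simulate_hu(1, c(water = 1), params_kv_printed), 0)
  expect_equal(simulate_hu(2, c(mineral = 1), params_kv_printed), 2209.6)
  # adipose surrogate at its table density: model prediction, not measurement
  expect_equal(simulate_hu(0.958, c(water = 0.3, lipid = 0.55, protein = 0.15),
                           params_kv_printed),
               -77.115, tolerance = 1e-3)
  set.seed(8)
  for (i in 1:10) {
    rho <- runif(1, 0.3, 2.5)
    w <- as.numeric(sample_tissue_compositions(
      c(water = 0.4, lipid = 0.2, protein = 0.2, mineral = 0.2),
      variation = 0.9, n = 1)[1, ])
    comp <- molecular_composition(w[1], w[2], w[3], w[4])
    expect_equal(hu_rho_from_hu(simulate_hu(rho, comp, params_kv_printed), rho),
                 hu_rho_from_molecular(comp, params_kv_printed),
                 tolerance = 1e-9)
  }
})
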