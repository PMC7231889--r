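test_that("pore-block residuals obey the closed form and its identities", {
  expect_equal(residual_fraction(0, 1, 1), 1)
  expect_equal(residual_fraction(1, 1, 1), 0.5)
  expect_equal(residual_fraction(10, 10, 2), 0.5)
  expect_error(residual_fraction(-1, 1, 1), ">= 0")
  expect_error(residual_fraction(1, 0, 1), "> 0")
  # monotone non-increasing in dose; bounded in (0, 1]
  conc <- seq(0, 50, 0.5)
  r <- residual_fraction(conc, ic50 = 2, hill = 0.8)
  expect_true(all(diff(r) <= 0))
  expect_true(all(r > 0 & r <= 1))
  # steeper Hill blocks more above the IC50
  expect_lt(residual_fraction(10, 2, 2), residual_fraction(10, 2, 1))
  # closed form agrees with numerical inversion of the dose-response
  for (r0 in c(0.9, 0.5, 0.2, 0.05)) {
    conc <- uniroot(function(c) residual_fraction(c, 3, 1.3) - r0,
                    c(1e-6, 1e6), tol = 1e-12)$root
    expect_equal(3 * (1 / r0 - 1)^(1 / 1.3), conc, tolerance = 1e-6)
  }
})

test_that("the packaged bepridil spec reproduces the printed residual anchor", {
  d <- default_drug("bepridil")
  expect_equal(residual_fraction(10, d$channels$I_CaL$ic50_um,
                                 d$channels$I_CaL$hill), 0.32, tolerance = 1e-3)
  # dofetilide D4 blocks about 80% of I_Kr
  dof <- default_drug("dofetilide")
  r <- residual_fraction(max(dof$doses_um), dof$channels$I_Kr$ic50_um,
                         dof$channels$I_Kr$hill)
  expect_equal(1 - r, 0.80, tolerance = 0.03)
})

test_that("drug application scales only targeted conductances, never upward", {
  p <- default_parameters()
  d <- default_drug("bepridil")
  expect_equal(apply_drug(p, d, 0), p)
  expect_error(apply_drug(p, d, 5), "not in the spec")
  p2 <- apply_drug(p, d, 5, ad_hoc = TRUE)
  expect_true(all(p2$constants[c("g_Kr", "g_CaL", "g_Na", "g_NaL")] <=
                  p$constants[c("g_Kr", "g_CaL", "g_Na", "g_NaL")]))
  expect_equal(unname(p2$constants["g_K1"]), unname(p$constants["g_K1"]))
  # overriding the I_CaL block to 1.0 leaves I_CaL untouched while the other
  # blocks stay in force
  d2 <- modulate_channel_block(d, "I_CaL", 1.0)
  p3 <- apply_drug(p, d2, 10)
  expect_equal(unname(p3$constants["g_CaL"]), unname(p$constants["g_CaL"]))
  expect_lt(unname(p3$constants["g_Kr"]), unname(p$constants["g_Kr"]) * 0.05)
  expect_error(modulate_channel_block(d, "I_K1", 0.5), "does not target")
  expect_error(modulate_channel_block(d, "I_CaL", 1.5), "0, 1")
  # an override equal to the computed residual is a no-op
  r <- residual_fraction(10, d$channels$I_CaL$ic50_um, d$channels$I_CaL$hill)
  expect_equal(apply_drug(p, modulate_channel_block(d, "I_CaL", r), 10),
               apply_drug(p, d, 10))
})

test_that("drug specs round-trip through YAML and validate", {
  d <- default_drug("diltiazem")
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name = d$name,
                        channels = d$channels,
                        doses_um = d$doses_um), f)
  d2 <- read_drug(f)
  expect_equal(d2$channels, d$channels)
  expect_equal(d2$doses_um, d$doses_um)
  expect_error(new_drug("x", list(I_Kr = list(ic50_um = 1, hill = 1)),
                        c(2, 1)), "sorted|increasing|FALSE")
  expect_error(new_drug("x", list(I_zz = list(ic50_um = 1, hill = 1)), 1),
               "unknown current")
})

test_that("the classifier labels every planted phenotype correctly", {
  # 200 randomized fixtures, constructed unambiguously far from thresholds
  set.seed(77)
  kinds <- rep(c("none", "ead", "repol_failure", "quiescent", "residual"), 40)
  for (kind in kinds) {
    fx <- make_synthetic_trace(
      cl_ms = sample(seq(1200, 2400, 100), 1),
      n_beats = sample(14:18, 1),
      mdp = runif(1, -82, -72),
      peak_vm = runif(1, 15, 40),
      repol_ms = sample(seq(300, 600, 50), 1),
      abnormality = kind,
      ead_level_mv = runif(1, -52, -44),
      quiescent_level_mv = runif(1, -75, -60),
      residual_peak_mv = runif(1, -30, -10))
    ph <- classify_phenotype(fx$trace)
    expect_equal(ph$primary, fx$label, label = kind)
    expect_true(ph$primary %in% c("OK", "Q", "RA", "IRR", "RESAC"))
  }
})

test_that("irregular rhythms and the residual/quiescence boundary classify", {
  irr <- make_synthetic_trace(cl_ms = c(1000, 3000), n_beats = 12)
  expect_equal(classify_phenotype(irr$trace)$primary, "IRR")
  steady <- make_synthetic_trace(cl_ms = c(1000, 1100), n_beats = 16)
  expect_equal(classify_phenotype(steady$trace)$primary, "OK")
  # peaks at -20 mV: residual activity; peaks at -45 mV: quiescence
  res <- make_synthetic_trace(abnormality = "residual", residual_peak_mv = -20,
                              n_beats = 16)
  expect_equal(classify_phenotype(res$trace)$primary, "RESAC")
  qui <- make_synthetic_trace(abnormality = "residual", residual_peak_mv = -45,
                              n_beats = 16)
  expect_equal(classify_phenotype(qui$trace)$primary, "Q")
  expect_error(classify_phenotype(
    make_synthetic_trace(n_beats = 5, cl_ms = 1000)$trace), "15 s")
})

test_that("EAD counting reports the planted hump exactly once per beat", {
  fx <- make_synthetic_trace(abnormality = "ead", n_beats = 16,
                             ead_level_mv = -50)
  ph <- classify_phenotype(fx$trace)
  expect_equal(ph$primary, "RA")
  expect_equal(ph$ead_count, 1)
  # a hump below the -55 mV rule is not an EAD
  low <- make_synthetic_trace(abnormality = "ead", n_beats = 16,
                              ead_level_mv = -60)
  expect_equal(classify_phenotype(low$trace)$ead_count, 0)
})

test_that("dose-0 trials leave an accepted-like member beating normally", {
  p <- adapted21_params()
  member <- list(id = "base", params = p,
                 steady_state = initial_state("steady_21c"))
  d <- default_drug("dofetilide")
  trial <- run_population_trial(list(member), d, doses = d$doses_um[1],
                                duration = 60)
  expect_equal(sum(trial$counts[1, c("OK", "Q", "RA", "IRR", "RESAC", "failed")]), 1)
  expect_true(all(rowSums(trial$counts[, c("OK", "Q", "RA", "IRR", "RESAC",
                                           "failed")]) == 1))
})
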