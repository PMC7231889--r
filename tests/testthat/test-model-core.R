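test_that("zero conductances give zero currents and a stationary state", {
  p <- default_parameters()
  p$constants[unname(current_conductance_map())] <- 0
  # leaks and SR fluxes included: V_leak, V_up are part of the map above
  st <- initial_state("diastolic")
  cur <- compute_currents(st, p)
  expect_true(all(abs(cur) == 0))
  d <- model_rhs(st, p)
  expect_equal(unname(d[["Vm"]]), 0)
  expect_equal(unname(d[c("Cai", "Ca_SR", "Nai")]), c(0, 0, 0))
})

test_that("invalid states are rejected with the offending component named", {
  p <- default_parameters()
  st <- initial_state("diastolic")
  st["Cai"] <- NaN
  expect_error(compute_currents(st, p), "Cai")
  st <- initial_state("diastolic"); st["Nai"] <- -1
  expect_error(model_rhs(st, p), "positive")
  expect_error(model_rhs(initial_state("diastolic"), p, stim = Inf), "finite")
})

test_that("compiled currents match an independent equation transcription", {
  p <- default_parameters()
  for (st in random_states(100, seed = 11)) {
    got <- compute_currents(st, p)
    want <- oracle_eval(st, p)$currents
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("compiled derivatives match the oracle, including at 21 C with scaling", {
  p <- adapt_to_environment(default_parameters(),
                            environment_conditions(21, 135, 5.4, 1.33))
  set.seed(3)
  sc <- setNames(runif(22, 0.5, 2), scalable_parameter_names())
  p <- apply_scaling(p, sc)
  for (st in random_states(50, seed = 12)) {
    got <- model_rhs(st, p, stim = 2)
    want <- oracle_eval(st, p, stim = 2)$derivs
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("dVm/dt is minus the signed current sum (rhs consistency)", {
  p <- default_parameters()
  membrane <- c("I_Na", "I_NaL", "I_f", "I_CaL", "I_to", "I_Kr", "I_Ks",
                "I_K1", "I_NCX", "I_NaK", "I_pCa", "I_bNa", "I_bCa")
  for (st in random_states(200, seed = 13)) {
    cur <- compute_currents(st, p, stim = 5)
    d <- model_rhs(st, p, stim = 5)
    expect_equal(unname(d[["Vm"]]), -(sum(cur[membrane]) - 5), tolerance = 1e-12)
  }
})

test_that("rhs and the integrator agree to first order (explicit Euler probe)", {
  p <- default_parameters()
  st <- initial_state("steady_37c")
  d <- model_rhs(st, p)
  h <- 1e-6
  tr <- run_simulation(p, st, protocol("nonpaced", duration = h, record_step = h))
  vm_pred <- st[["Vm"]] * 1000 + d[["Vm"]] * h * 1000
  expect_equal(tr$vm[length(tr$vm)], vm_pred, tolerance = 1e-6)
})

test_that("Ca2+ is conserved between cytosol and SR through I_rel", {
  # with SERCA, leak and all membrane Ca2+ pathways blocked, release moves
  # Ca2+ from SR to cytosol only: buffered fluxes must balance via the
  # volume ratio
  p <- default_parameters()
  p <- block_currents(p, c(I_up = 0, I_leak = 0, I_CaL = 0, I_bCa = 0,
                           I_pCa = 0, I_NCX = 0))
  for (st in random_states(20, seed = 14)) {
    d <- model_rhs(st, p)
    o <- oracle_eval(st, p)
    k <- p$constants
    buf_c <- 1 / (1 + k[["Buf_C"]] * k[["Kbuf_C"]] / (st[["Cai"]] + k[["Kbuf_C"]])^2)
    buf_sr <- 1 / (1 + k[["Buf_SR"]] * k[["Kbuf_SR"]] / (st[["Ca_SR"]] + k[["Kbuf_SR"]])^2)
    # free-Ca rates, un-buffered, must cancel after volume weighting
    expect_equal(d[["Cai"]] / buf_c * k[["Vc"]],
                 -d[["Ca_SR"]] / buf_sr * k[["V_SR"]], tolerance = 1e-9)
    expect_equal(unname(o$currents["I_up"]), 0)
  }
})

test_that("evaluation is pure: inputs are never mutated", {
  p <- default_parameters()
  st <- initial_state("diastolic")
  p_copy <- unserialize(serialize(p, NULL))
  st_copy <- st
  invisible(compute_currents(st, p))
  invisible(model_rhs(st, p))
  invisible(apply_scaling(p, setNames(rep(1.5, 22), scalable_parameter_names())))
  invisible(block_currents(p, c(I_Kr = 0.5)))
  expect_identical(st, st_copy)
  expect_identical(p, p_copy)
})

test_that("raising the SERCA half-saturation constant lowers uptake at fixed Cai", {
  p <- default_parameters()
  sc <- setNames(rep(1, 22), scalable_parameter_names())
  sc["K_up"] <- 2
  p2 <- apply_scaling(p, sc)
  st <- initial_state("steady_37c")
  expect_lt(compute_currents(st, p2)[["I_up"]], compute_currents(st, p)[["I_up"]])
})

test_that("probe state at -70 mV matches the oracle current-by-current", {
  p <- default_parameters()
  st <- steady_gate_state(-0.070, p)
  got <- compute_currents(st, p)
  want <- oracle_eval(st, p)$currents
  expect_equal(got, want, tolerance = 1e-10)
  # gates really are stationary there (except Ca-coupled ones)
  d <- model_rhs(st, p)
  vgates <- c("m", "h", "j", "d", "f1", "f2", "Xr1", "Xr2", "Xs", "Xf",
              "q", "r", "mL", "hL")
  expect_true(all(abs(d[vgates]) < 1e-4))
})
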