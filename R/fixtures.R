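# Synthetic piecewise-linear AP/CaTr traces with exact analytic ground truth.
# Piecewise-linear shapes are chosen deliberately: every level crossing has a
# closed form, so biomarker extraction can be tested to interpolation
# exactness without the ODE solver.

#' Generate a synthetic AP/CaTr trace with known ground truth
#'
#' Builds `n_beats` template beats: an instantaneous-slope linear upstroke
#' from MDP to peak, a linear repolarization back to MDP, and a flat
#' diastole; the Ca transient rises linearly from its diastolic level to the
#' peak and decays linearly. Optionally plants one abnormality.
#'
#' @param cl_ms cycle length in ms, or a vector (recycled) for irregular
#'   rhythms.
#' @param n_beats number of beats (the trailing diastole makes the last beat
#'   complete only if another upstroke follows; with `n_beats` upstrokes
#'   there are `n_beats - 1` complete beats).
#' @param mdp,peak_vm diastolic and peak membrane potential, mV.
#' @param upstroke_ms,repol_ms upstroke and repolarization durations, ms.
#' @param ca_diastolic_nm,ca_peak_nm diastolic and peak Cai, nM.
#' @param ca_delay_ms onset delay of the Ca transient after the upstroke, ms.
#' @param ca_rise_ms,ca_decay_ms CaTr rise and decay durations, ms.
#' @param abnormality one of "none", "ead", "repol_failure", "quiescent",
#'   "residual".
#' @param ead_level_mv,ead_width_ms planted extra-peak level and width.
#' @param quiescent_level_mv flat potential for the quiescent fixture.
#' @param residual_peak_mv AP peak for the residual-activity fixture.
#' @param step_ms sampling step, ms.
#' @return list with `trace` (a `cm_trace`), `truth` (named list of exact
#'   biomarkers, ms/mV/nM) and `label` (expected phenotype).
#' @export
make_synthetic_trace <- function(cl_ms = 1000, n_beats = 21, mdp = -75,
                                 peak_vm = 30, upstroke_ms = 2, repol_ms = 450,
                                 ca_diastolic_nm = 100, ca_peak_nm = 260,
                                 ca_delay_ms = 10, ca_rise_ms = 200,
                                 ca_decay_ms = 600,
                                 abnormality = c("none", "ead", "repol_failure",
                                                 "quiescent", "residual"),
                                 ead_level_mv = -50, ead_width_ms = 120,
                                 quiescent_level_mv = -70,
                                 residual_peak_mv = -20, step_ms = 1) {
  abnormality <- match.arg(abnormality)
  cls <- rep_len(cl_ms, n_beats)
  if (any(cls <= upstroke_ms + repol_ms))
    stop("cycle length must exceed upstroke + repolarization")
  if (any(cls <= ca_delay_ms + ca_rise_ms + ca_decay_ms))
    stop("cycle length must exceed the Ca-transient duration")
  if (abnormality == "residual") peak_vm <- residual_peak_mv

  # a repolarization failure must dominate the trailing 15 s window
  total_ms <- sum(cls) + if (abnormality == "repol_failure") 16000 else 200
  tt <- seq(0, total_ms, by = step_ms)

  if (abnormality == "quiescent") {
    vm <- rep(quiescent_level_mv, length(tt))
    cai <- rep(ca_diastolic_nm * 1e-6, length(tt))
    tr <- new_trace(tt / 1000, vm, cai, rep(0, length(tt)),
                    protocol("nonpaced", duration = total_ms / 1000),
                    final_state = NULL,
                    metadata = list(fixture = "quiescent"))
    return(list(trace = tr, truth = list(), label = "Q"))
  }

  onsets <- cumsum(c(100, cls))[seq_len(n_beats)]  # upstroke start times (ms)
  vnodes_t <- 0; vnodes_v <- mdp
  cnodes_t <- 0; cnodes_c <- ca_diastolic_nm
  for (i in seq_len(n_beats)) {
    t0 <- onsets[i]
    fail_this <- abnormality == "repol_failure" && i == n_beats
    vnodes_t <- c(vnodes_t, t0, t0 + upstroke_ms)
    vnodes_v <- c(vnodes_v, mdp, peak_vm)
    if (fail_this) {
      vnodes_t <- c(vnodes_t, t0 + upstroke_ms + repol_ms, total_ms)
      vnodes_v <- c(vnodes_v, -20, -20)
    } else {
      vnodes_t <- c(vnodes_t, t0 + upstroke_ms + repol_ms)
      vnodes_v <- c(vnodes_v, mdp)
      if (abnormality == "ead" && i == floor(n_beats / 2)) {
        # interposed hump during diastole, well clear of both upstrokes
        tm <- t0 + upstroke_ms + repol_ms + 150
        vnodes_t <- c(vnodes_t, tm, tm + ead_width_ms / 2, tm + ead_width_ms)
        vnodes_v <- c(vnodes_v, mdp, ead_level_mv, mdp)
      }
    }
    c0 <- t0 + ca_delay_ms
    cnodes_t <- c(cnodes_t, c0, c0 + ca_rise_ms, c0 + ca_rise_ms + ca_decay_ms)
    cnodes_c <- c(cnodes_c, ca_diastolic_nm, ca_peak_nm, ca_diastolic_nm)
  }
  vnodes_t <- c(vnodes_t, total_ms); vnodes_v <- c(vnodes_v, vnodes_v[length(vnodes_v)])
  cnodes_t <- c(cnodes_t, total_ms); cnodes_c <- c(cnodes_c, ca_diastolic_nm)

  vm <- approx(vnodes_t, vnodes_v, tt, rule = 2, ties = "ordered")$y
  cai <- approx(cnodes_t, cnodes_c, tt, rule = 2, ties = "ordered")$y * 1e-6
  dvdt <- c(diff(vm) / diff(tt), 0)  # mV/ms == V/s
  tr <- new_trace(tt / 1000, vm, cai, dvdt,
                  protocol("nonpaced", duration = total_ms / 1000),
                  final_state = NULL,
                  metadata = list(fixture = abnormality))

  amp <- peak_vm - mdp
  camp <- ca_peak_nm - ca_diastolic_nm
  apd <- function(x) upstroke_ms + (x / 100) * repol_ms
  truth <- list(
    AP_CL = mean(diff(onsets)), APD30 = apd(30), APD50 = apd(50),
    APD90 = apd(90), APD10 = apd(10),
    AP_Tri90_30 = apd(90) - apd(30),
    AP_Tri_ratio = (apd(40) - apd(30)) / (apd(80) - apd(70)),
    APA = amp, MDP = mdp, AP_peak = peak_vm,
    dVdt_max = amp / upstroke_ms,
    CaTr_CL = mean(diff(onsets)),
    # the CaTr onset is the 10%-amplitude foot of the rise
    CTD30 = 0.9 * ca_rise_ms + 0.30 * ca_decay_ms,
    CTD50 = 0.9 * ca_rise_ms + 0.50 * ca_decay_ms,
    CTD90 = 0.9 * ca_rise_ms + 0.90 * ca_decay_ms,
    CaTr_Tri90_30 = 0.60 * ca_decay_ms,
    CaTr_tRise0peak = 0.9 * ca_rise_ms,
    CaTr_tDecay90_10 = 0.8 * ca_decay_ms,
    CaTr_amplitude = camp, CaTr_diastolic = ca_diastolic_nm
  )
  label <- switch(abnormality,
                  none = "OK",
                  ead = "RA",
                  repol_failure = "RA",
                  residual = "RESAC",
                  quiescent = "Q")
  if (length(unique(cls)) > 1 &&
      any(abs(diff(diff(onsets))) / diff(onsets)[-(n_beats - 1)] > 1.5) &&
      label == "OK")
    label <- "IRR"
  list(trace = tr, truth = truth, label = label)
}

# assemble a cm_biomarkers object from exact values (fixture helper)
fixture_biomarkers <- function(values, n_beats = 21) {
  tab <- data.frame(biomarker = .biomarker_names,
                    mean = NA_real_, sd = 0)
  tab$mean[match(names(values), tab$biomarker)] <- unlist(values)
  structure(list(table = tab, n_beats = n_beats), class = "cm_biomarkers")
}

#' Synthesize population members with a known acceptance rate
#'
#' Builds calibration-ready member records whose biomarker sets lie inside
#' every bound of `ranges` with probability `accept_fraction` (rejects get a
#' single out-of-range biomarker), so calibration logic can be tested without
#' any simulation.
#'
#' @param n number of members.
#' @param ranges a `cm_range_table`.
#' @param accept_fraction expected accepted fraction in \[0, 1\].
#' @param seed integer seed.
#' @return list of member records (as from [simulate_member()]), each with a
#'   `truth_accept` flag.
#' @export
make_population_fixture <- function(n, ranges = default_range_table(),
                                    accept_fraction = 0.5, seed = 1) {
  stopifnot(accept_fraction >= 0, accept_fraction <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  accept <- runif(n) < accept_fraction
  bounds <- function(b, proto) {
    r <- ranges[ranges$biomarker == b & ranges$protocol == proto, ]
    c(r$lb[1], r$ub[1])
  }
  mk <- function(ok) {
    vals <- list(nonpaced = list(), paced = list())
    for (proto in c("nonpaced", "paced")) {
      for (b in .mode_biomarkers("AP_CaTr", proto)) {
        bb <- bounds(b, proto)
        vals[[proto]][[b]] <- mean(bb)
      }
    }
    vals$nonpaced$AP_peak <- 37; vals$nonpaced$APA <- 100
    vals$nonpaced$MDP <- -73; vals$nonpaced$dVdt_max <- 20
    vals$paced$AP_peak <- 37; vals$paced$AP_CL <- 2000; vals$paced$CaTr_CL <- 2000
    if (!ok) {
      # violate exactly one randomly chosen bound
      proto <- sample(c("nonpaced", "paced"), 1)
      b <- sample(.mode_biomarkers("AP_CaTr", proto), 1)
      bb <- bounds(b, proto)
      vals[[proto]][[b]] <- bb[2] + 0.1 * (bb[2] - bb[1])
    }
    vals
  }
  lapply(seq_len(n), function(i) {
    vals <- mk(accept[i])
    list(id = sprintf("f%04d", i),
         scaling = setNames(runif(22, 0.5, 2), scalable_parameter_names()),
         status = "simulated",
         biomarkers_nonpaced = fixture_biomarkers(vals$nonpaced),
         biomarkers_paced = fixture_biomarkers(vals$paced),
         steady_state = NULL, paced_captured = TRUE,
         truth_accept = accept[i])
  })
}
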