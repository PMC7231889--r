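# brute-force crossing finder: dense sample scan, independent of the
# interpolation code under test
brute_cross_down <- function(tt, vv, level, from) {
  i0 <- which(tt >= from)[1]
  for (i in seq(i0, length(tt) - 1)) {
    if (vv[i] >= level && vv[i + 1] < level) {
      f <- (level - vv[i]) / (vv[i + 1] - vv[i])
      return(tt[i] + f * (tt[i + 1] - tt[i]))
    }
  }
  NA_real_
}

test_that("segmentation drops the incomplete last beat and handles empties", {
  fx <- make_synthetic_trace(n_beats = 22, cl_ms = 1000)
  segs <- segment_beats(fx$trace)
  expect_length(segs, 21)
  flat <- new_trace(seq(0, 20, 0.01), rep(-70, 2001), rep(1e-4, 2001),
                    rep(0, 2001), protocol("nonpaced", duration = 20), NULL)
  expect_length(segment_beats(flat), 0)
  expect_null(summarize_biomarkers(flat))
})

test_that("an interposed sub-threshold hump does not split a beat", {
  fx <- make_synthetic_trace(n_beats = 8, cl_ms = 1500, abnormality = "ead",
                             ead_level_mv = -50)
  segs <- segment_beats(fx$trace)
  expect_length(segs, 8 - 1)
})

test_that("closed-form line crossings are recovered exactly", {
  # near-instant rise to +30 mV, linear fall to -70 mV over 500 ms:
  # amplitude 100 mV, APD90 crosses -60 mV at 450 ms, APD30 crosses 0 at 150
  fx <- make_synthetic_trace(n_beats = 4, cl_ms = 1200, mdp = -70,
                             peak_vm = 30, upstroke_ms = 1, repol_ms = 500)
  bm <- summarize_biomarkers(fx$trace)
  expect_equal(biomarker_value(bm, "APA"), 100)
  # crossings sit exactly at 450 / 150 ms past the peak; the activation
  # anchor is grid-quantized, so allow one record step
  expect_lt(abs(biomarker_value(bm, "APD90") - 450), 1 + 1e-9)
  expect_lt(abs(biomarker_value(bm, "APD30") - 150), 1 + 1e-9)
  expect_equal(biomarker_value(bm, "AP_Tri90_30"), 300, tolerance = 1e-9)
})

test_that("piecewise-linear fixtures reproduce ground truth to 1e-9 s", {
  for (seed in 1:5) {
    set.seed(seed)
    fx <- make_synthetic_trace(
      n_beats = 6,
      cl_ms = sample(seq(1400, 2600, 100), 1),
      mdp = runif(1, -80, -70), peak_vm = runif(1, 20, 40),
      upstroke_ms = 2, repol_ms = sample(seq(300, 600, 50), 1),
      ca_rise_ms = sample(seq(150, 250, 50), 1),
      ca_decay_ms = sample(seq(500, 900, 100), 1))
    bm <- summarize_biomarkers(fx$trace)
    expect_equal(bm$n_beats, 5)
    # crossing-differences and onset-anchored durations are exact
    for (b in c("AP_Tri90_30", "AP_Tri_ratio", "CTD30", "CTD50", "CTD90",
                "CaTr_Tri90_30", "CaTr_tRise0peak", "CaTr_tDecay90_10",
                "CaTr_amplitude", "CaTr_diastolic", "APA", "MDP", "AP_peak"))
      expect_equal(biomarker_value(bm, b), fx$truth[[b]], tolerance = 1e-9,
                   label = b)
    expect_equal(biomarker_value(bm, b <- "CaTr_CL"), fx$truth[[b]],
                 tolerance = 1e-9)
    # activation-anchored durations are exact up to one record step
    for (b in c("APD30", "APD50", "APD90"))
      expect_lt(abs(biomarker_value(bm, b) - fx$truth[[b]]), 1 + 1e-9)
    expect_equal(biomarker_value(bm, "AP_CL"), fx$truth$AP_CL, tolerance = 1e-6)
  }
})

test_that("crossing search agrees with a brute-force scan on random beats", {
  set.seed(99)
  for (rep in 1:20) {
    fx <- make_synthetic_trace(n_beats = 3, cl_ms = 2000,
                               mdp = runif(1, -85, -65),
                               peak_vm = runif(1, 10, 45),
                               repol_ms = runif(1, 250, 700))
    tr <- fx$trace
    segs <- segment_beats(tr)
    b <- segs[[2]]
    amp <- b$peak_Vm - b$MDP_post
    x <- runif(1, 0.1, 0.9)
    lev <- b$peak_Vm - x * amp
    got <- brute_cross_down(tr$time, tr$vm, lev, b$peak_time)
    cross <- ipscpop:::.cross_down(tr$time[b$i_start:b$i_end],
                                   tr$vm[b$i_start:b$i_end], lev,
                                   which.max(tr$vm[b$i_start:b$i_end]))
    expect_equal(cross, got, tolerance = 1e-9)
  }
})

test_that("duration ordering and triangulation identities hold", {
  bm <- summarize_biomarkers(baseline37_trace())
  expect_lte(biomarker_value(bm, "APD30"), biomarker_value(bm, "APD50"))
  expect_lte(biomarker_value(bm, "APD50"), biomarker_value(bm, "APD90"))
  expect_lte(biomarker_value(bm, "CTD30"), biomarker_value(bm, "CTD50"))
  expect_lte(biomarker_value(bm, "CTD50"), biomarker_value(bm, "CTD90"))
  expect_equal(biomarker_value(bm, "AP_Tri90_30"),
               biomarker_value(bm, "APD90") - biomarker_value(bm, "APD30"),
               tolerance = 1e-6)
})

test_that("identical beats give zero dispersion; alternating CLs average", {
  fx <- make_synthetic_trace(n_beats = 22, cl_ms = 1000)
  bm <- summarize_biomarkers(fx$trace)
  expect_equal(bm$n_beats, 20)
  for (b in c("AP_CL", "APD90", "CTD90", "CaTr_amplitude"))
    expect_lt(bm$table$sd[match(b, bm$table$biomarker)], 1e-9)

  alt <- make_synthetic_trace(n_beats = 21, cl_ms = c(1000, 1200))
  bma <- summarize_biomarkers(alt$trace)
  cls <- rep_len(c(1000, 1200), 21)[1:20]
  expect_equal(biomarker_value(bma, "AP_CL"), mean(cls), tolerance = 1e-6)
  expect_equal(biomarker_value(bma, "AP_CL", "sd"), sd(cls), tolerance = 1e-4)
})

test_that("halving the record step barely moves solver-derived biomarkers", {
  p <- default_parameters()
  st <- initial_state("steady_37c")
  b1 <- summarize_biomarkers(run_simulation(p, st,
          protocol("nonpaced", duration = 20, record_step = 0.002)))
  b2 <- summarize_biomarkers(run_simulation(p, st,
          protocol("nonpaced", duration = 20, record_step = 0.001)))
  for (b in c("APD90", "APD30", "CTD90", "AP_CL"))
    expect_lt(abs(biomarker_value(b1, b) - biomarker_value(b2, b)), 1)
})

test_that("biomarker tables serialize with stable columns", {
  fx <- make_synthetic_trace(n_beats = 5)
  bm <- summarize_biomarkers(fx$trace)
  f <- withr::local_tempfile(fileext = ".csv")
  df <- write_biomarker_table(list(a = bm, b = NULL), f)
  expect_equal(df$n_beats, c(4, 0))
  back <- read.csv(f)
  expect_equal(names(back), names(df))
  expect_equal(back$APD90_mean[1], biomarker_value(bm, "APD90"))
})
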