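test_that("Latin hypercube sampling is stratified, bounded and reproducible", {
  expect_length(sample_scalings(0), 0)
  sc <- sample_scalings(1000, seed = 5)
  m <- do.call(rbind, sc)
  expect_equal(dim(m), c(1000, 22))
  expect_true(all(m >= 0.5 & m <= 2))
  # uniform moments: per-entry mean within 3 SE of 1.25
  se <- (2 - 0.5) / sqrt(12) / sqrt(1000)
  expect_true(all(abs(colMeans(m) - 1.25) < 3 * se))
  # marginal stratification: exactly one draw per 1/n slab in every dimension
  bins <- apply(m, 2, function(x) table(cut(x, breaks = seq(0.5, 2, length.out = 1001))))
  expect_true(all(bins == 1))
  expect_identical(sample_scalings(10, seed = 42), sample_scalings(10, seed = 42))
  expect_false(identical(sample_scalings(10, seed = 42), sample_scalings(10, seed = 43)))
})

test_that("range tables follow the min(mean - 2SD) / max(mean + 2SD) rule", {
  one <- data.frame(biomarker = "APD90", protocol = "nonpaced",
                    mean = 500, sd = 50)
  rt <- build_range_table(one)
  expect_equal(rt$lb, 400); expect_equal(rt$ub, 600)
  two <- rbind(one, data.frame(biomarker = "APD90", protocol = "nonpaced",
                               mean = 800, sd = 100))
  rt2 <- build_range_table(two)
  expect_equal(rt2$lb, 400); expect_equal(rt2$ub, 1000)
  expect_error(build_range_table(one[0, ]), "no per-sample")
  expect_error(build_range_table(transform(one, sd = -1)), "SD")
})

test_that("the packaged experimental ranges carry the printed bounds", {
  rt <- default_range_table()
  r <- rt[rt$biomarker == "APD90" & rt$protocol == "nonpaced", ]
  expect_equal(c(r$lb, r$ub), c(485.1, 1393.8))
  r <- rt[rt$biomarker == "AP_CL" & rt$protocol == "nonpaced", ]
  expect_equal(c(r$lb, r$ub), c(1310.2, 12798.5))
  expect_false(any(rt$biomarker %in% c("AP_CL", "CaTr_CL") & rt$protocol == "paced"))
})

test_that("calibration matches a brute-force per-bound scan", {
  members <- make_population_fixture(150, accept_fraction = 0.5, seed = 21)
  ranges <- default_range_table()
  for (mode in c("AP_CaTr", "AP_only", "CaTr_only")) {
    got <- vapply(calibrate(members, ranges, mode), `[[`, character(1), "status")
    # independent scan
    want <- vapply(members, function(m) {
      for (proto in c("nonpaced", "paced")) {
        bmset <- if (proto == "nonpaced") m$biomarkers_nonpaced else m$biomarkers_paced
        bl <- ipscpop:::.mode_biomarkers(mode, proto)
        for (b in bl) {
          r <- ranges[ranges$biomarker == b & ranges$protocol == proto, ]
          v <- biomarker_value(bmset, b)
          if (!(v >= r$lb && v <= r$ub)) return("rejected")
        }
      }
      if (mode != "CaTr_only") {
        pk <- biomarker_value(m$biomarkers_nonpaced, "AP_peak")
        if (!(pk >= 17 && pk <= 57.7)) return("rejected")
      }
      "accepted"
    }, character(1))
    expect_equal(got == "accepted", want == "accepted",
                 label = paste("mode", mode))
  }
})

test_that("acceptance decisions respect the fixture's planted truth", {
  members <- make_population_fixture(120, accept_fraction = 0.4, seed = 8)
  st <- vapply(calibrate(members, default_range_table(), "AP_CaTr"),
               `[[`, character(1), "status")
  expect_equal(st == "accepted",
               vapply(members, `[[`, logical(1), "truth_accept"))
})

test_that("the combined calibration is the intersection of the single modes", {
  members <- make_population_fixture(200, accept_fraction = 0.6, seed = 31)
  # scatter extra violations so the three modes differ
  ranges <- default_range_table()
  stat <- sapply(c("AP_CaTr", "AP_only", "CaTr_only"), function(md)
    vapply(calibrate(members, ranges, md), `[[`, character(1), "status"))
  both <- stat[, "AP_only"] == "accepted" & stat[, "CaTr_only"] == "accepted"
  expect_equal(stat[, "AP_CaTr"] == "accepted", both)
})

test_that("quiescent, failed and non-captured members are rejected", {
  members <- make_population_fixture(4, accept_fraction = 1, seed = 2)
  members[[1]]$biomarkers_nonpaced <- NULL
  members[[2]]$status <- "solver_failed"
  members[[3]]$paced_captured <- FALSE
  st <- vapply(calibrate(members, default_range_table(), "AP_CaTr"),
               `[[`, character(1), "status")
  expect_equal(st, c("quiescent", "solver_failed", "rejected:no_capture",
                     "accepted"))
})

test_that("group comparison reports relative median shifts above threshold", {
  a <- replicate(11, setNames(rep(1, 22), scalable_parameter_names()),
                 simplify = FALSE)
  expect_equal(nrow(compare_groups(a, a)), 0)
  b <- lapply(a, function(x) { x["g_K1"] <- 1.2; x })
  out <- compare_groups(b, a)
  expect_equal(out$parameter, "g_K1")
  expect_equal(out$delta, 0.2, tolerance = 1e-12)
  expect_error(compare_groups(list(), a), "non-empty")
})
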