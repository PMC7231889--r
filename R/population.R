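# Population-of-models construction and experimental-range calibration.

#' Sample population scaling vectors by Latin hypercube
#'
#' Draws `n` vectors of 22 dimensionless multipliers, one per
#' population-scalable parameter, uniform on \[low, high\] via Latin hypercube
#' sampling. Fully reproducible from `seed`.
#'
#' @param n number of candidate models.
#' @param low,high sampling range (50--200% of baseline by default).
#' @param seed integer seed.
#' @return list of named scaling vectors.
#' @export
sample_scalings <- function(n, low = 0.5, high = 2.0, seed = 1) {
  stopifnot(n >= 0, low > 0, low < high)
  if (n == 0) return(list())
  nm <- scalable_parameter_names()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  u <- lhs::randomLHS(n, length(nm))
  vals <- low + u * (high - low)
  lapply(seq_len(n), function(i) setNames(vals[i, ], nm))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Build a biomarker range table from per-sample statistics
#'
#' For every biomarker, LB = min over samples of (mean - 2 SD) and
#' UB = max over samples of (mean + 2 SD).
#'
#' @param per_sample_stats data.frame with columns `biomarker`, `protocol`
#'   ("nonpaced"/"paced"), `mean`, `sd`.
#' @param units optional named character vector biomarker -> units.
#' @return a `cm_range_table` (data.frame with biomarker, protocol, lb, ub,
#'   units).
#' @export
build_range_table <- function(per_sample_stats, units = NULL) {
  df <- per_sample_stats
  need <- c("biomarker", "protocol", "mean", "sd")
  if (!all(need %in% names(df))) stop("need columns: ", paste(need, collapse = ", "))
  if (!nrow(df)) stop("no per-sample statistics given")
  if (any(df$sd < 0)) stop("SDs must be >= 0")
  key <- interaction(df$biomarker, df$protocol, drop = TRUE)
  rows <- lapply(split(df, key), function(g) {
    data.frame(biomarker = g$biomarker[1], protocol = g$protocol[1],
               lb = min(g$mean - 2 * g$sd), ub = max(g$mean + 2 * g$sd),
               units = if (!is.null(units) && g$biomarker[1] %in% names(units))
                 units[[g$biomarker[1]]] else "ms")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_range_table(out)
}

validate_range_table <- function(df) {
  stopifnot(all(c("biomarker", "protocol", "lb", "ub", "units") %in% names(df)))
  bad <- df$lb >= df$ub
  if (any(bad))
    stop("lb >= ub for: ", paste(df$biomarker[bad], df$protocol[bad], collapse = "; "))
  structure(df[order(df$protocol, df$biomarker), , drop = FALSE],
            class = c("cm_range_table", "data.frame"))
}

#' The packaged experimental range table of the optical recordings
#'
#' Per-biomarker \[LB, UB\] bounds for the control nonpaced and paced (0.5 Hz)
#' protocols, plus the nonpaced AP-peak window used when calibrating with AP
#' biomarkers.
#' @return a `cm_range_table`.
#' @export
default_range_table <- function() {
  read_range_table(system.file("extdata", "experimental_ranges.csv",
                               package = "ipscpop"))
}

# biomarkers relevant to each calibration mode, per protocol
.mode_biomarkers <- function(mode, proto) {
  ap <- c("AP_CL", "APD90", "APD50", "APD30", "AP_Tri90_30")
  ca <- c("CaTr_CL", "CTD90", "CTD50", "CTD30", "CaTr_tRise0peak", "CaTr_Tri90_30")
  sel <- switch(mode, AP_only = ap, CaTr_only = ca, AP_CaTr = c(ap, ca),
                stop("unknown calibration mode: ", mode))
  if (proto == "paced") sel <- setdiff(sel, c("AP_CL", "CaTr_CL"))
  sel
}

#' Simulate one population member under the calibration protocols
#'
#' Applies the member's scaling vector to the (environment-adapted) baseline,
#' runs the 800 s nonpaced and 0.5 Hz paced steady-state protocols and
#' summarizes the last 20 beats of each.
#'
#' @param params baseline `cm_parameters` (already adapted to the experiment's
#'   environment).
#' @param scaling named 22-entry scaling vector.
#' @param id member id.
#' @param duration protocol duration in seconds.
#' @param keep trailing full-resolution window (s).
#' @param initial starting state (defaults to the packaged steady state for
#'   the parameter set's temperature).
#' @param record_step sampling step (s).
#' @param ranges optional `cm_range_table`: when given, the paced run is
#'   skipped for members whose nonpaced biomarkers already violate both the
#'   AP and the CaTr nonpaced bound sets (they are rejected in every
#'   calibration mode regardless).
#' @return a population-member record: list with id, scaling, biomarker
#'   summaries per protocol, the nonpaced final state and a status.
#' @export
simulate_member <- function(params, scaling, id = "m1", duration = 800,
                            keep = 300, initial = NULL, record_step = 0.005,
                            ranges = NULL) {
  pm <- apply_scaling(params, scaling)
  res <- list(id = id, scaling = scaling, status = "simulated",
              biomarkers_nonpaced = NULL, biomarkers_paced = NULL,
              steady_state = NULL, paced_captured = NA, paced_skipped = FALSE)
  np <- tryCatch(suppressWarnings(run_steady_state(pm,
          protocol("nonpaced", duration = duration, record_step = record_step,
                   keep = keep), initial = initial)),
        cm_integration_error = function(e) e, error = function(e) e)
  if (inherits(np, "error")) { res$status <- "solver_failed"; return(res) }
  res$steady_state <- np$final_state
  res$biomarkers_nonpaced <- summarize_biomarkers(np)
  # the paced protocol only matters for members still in contention after the
  # nonpaced bounds: quiescent candidates and members violating both the AP
  # and CaTr nonpaced bound sets are rejected regardless of the paced run
  if (is.null(res$biomarkers_nonpaced) ||
      (!is.null(ranges) && !.nonpaced_in_contention(res$biomarkers_nonpaced, ranges))) {
    res$paced_skipped <- TRUE
    return(res)
  }
  pp <- tryCatch(suppressWarnings(run_simulation(pm,
          if (is.null(initial)) np$final_state else initial,
          protocol("paced", pacing_rate = 0.5, duration = duration,
                   record_step = record_step, keep = keep))),
        cm_integration_error = function(e) e, error = function(e) e)
  if (inherits(pp, "error")) { res$status <- "solver_failed"; return(res) }
  res$biomarkers_paced <- summarize_biomarkers(pp)
  # 1:1 capture check: paced CL must equal the pacing period
  if (!is.null(res$biomarkers_paced)) {
    cl <- biomarker_value(res$biomarkers_paced, "AP_CL")
    res$paced_captured <- is.finite(cl) && abs(cl - 2000) < 100
  } else res$paced_captured <- FALSE
  res
}

#' Calibrate population members against experimental ranges
#'
#' A member is accepted iff every mode-relevant biomarker mean (nonpaced:
#' cycle lengths, durations, triangulations, rise time; paced: the same
#' without cycle lengths) lies within its \[LB, UB\] bound, and -- in the
#' AP-containing modes -- the nonpaced AP peak lies within the AP-peak
#' window. Quiescent and solver-failed members are rejected; members whose
#' paced run fails 1:1 capture are rejected with a distinct reason. The
#' rejection reason records the first violated bound.
#'
#' @param members list of member records from [simulate_member()].
#' @param ranges a `cm_range_table`.
#' @param mode one of "AP_only", "CaTr_only", "AP_CaTr".
#' @param ap_peak_window nonpaced AP-peak bounds (mV) for AP-containing modes.
#' @return the members, each with `status` set to "accepted" or
#'   "rejected:<reason>".
#' @export
calibrate <- function(members, ranges, mode = c("AP_CaTr", "AP_only", "CaTr_only"),
                      ap_peak_window = c(17.0, 57.7)) {
  mode <- match.arg(mode)
  stopifnot(inherits(ranges, "cm_range_table"))
  for (proto in c("nonpaced", "paced"))
    for (b in .mode_biomarkers(mode, proto))
      if (!any(ranges$biomarker == b & ranges$protocol == proto))
        stop("range table lacks ", proto, " bounds for ", b)
  lapply(members, function(m) {
    m$status <- .calibrate_one(m, ranges, mode, ap_peak_window)
    m
  })
}

# nonpaced prefilter: TRUE if the member passes the nonpaced bounds of the
# AP set (with the AP-peak window) or of the CaTr set
.nonpaced_in_contention <- function(bm, ranges, ap_peak_window = c(17.0, 57.7)) {
  pass_set <- function(mode) {
    for (b in .mode_biomarkers(mode, "nonpaced")) {
      r <- ranges[ranges$biomarker == b & ranges$protocol == "nonpaced", ]
      v <- biomarker_value(bm, b)
      if (!is.finite(v) || v < r$lb[1] || v > r$ub[1]) return(FALSE)
    }
    TRUE
  }
  pk <- biomarker_value(bm, "AP_peak")
  ap_ok <- pass_set("AP_only") && is.finite(pk) &&
    pk >= ap_peak_window[1] && pk <= ap_peak_window[2]
  ap_ok || pass_set("CaTr_only")
}

.calibrate_one <- function(m, ranges, mode, ap_peak_window) {
  if (identical(m$status, "solver_failed")) return("solver_failed")
  if (is.null(m$biomarkers_nonpaced)) return("quiescent")
  for (b in .mode_biomarkers(mode, "nonpaced")) {
    r <- ranges[ranges$biomarker == b & ranges$protocol == "nonpaced", ]
    v <- biomarker_value(m$biomarkers_nonpaced, b)
    if (!is.finite(v) || v < r$lb[1] || v > r$ub[1])
      return(paste0("rejected:nonpaced:", b))
  }
  if (mode %in% c("AP_only", "AP_CaTr")) {
    pk <- biomarker_value(m$biomarkers_nonpaced, "AP_peak")
    if (!is.finite(pk) || pk < ap_peak_window[1] || pk > ap_peak_window[2])
      return("rejected:nonpaced:AP_peak")
  }
  if (is.null(m$biomarkers_paced)) return("rejected:paced_quiescent")
  if (identical(m$paced_captured, FALSE)) return("rejected:no_capture")
  for (b in .mode_biomarkers(mode, "paced")) {
    r <- ranges[ranges$biomarker == b & ranges$protocol == "paced", ]
    v <- biomarker_value(m$biomarkers_paced, b)
    if (!is.finite(v) || v < r$lb[1] || v > r$ub[1])
      return(paste0("rejected:paced:", b))
  }
  "accepted"
}

#' Compare parameter distributions between two groups
#'
#' Per-parameter medians of the scaling factors; returns the parameters whose
#' relative median difference |median_a - median_b| / median_b exceeds the
#' threshold, sorted by |delta| descending.
#'
#' @param group_a,group_b lists of scaling vectors.
#' @param threshold relative difference cut-off (0.10 in the study).
#' @return data.frame with parameter, median_a, median_b, delta.
#' @export
compare_groups <- function(group_a, group_b, threshold = 0.10) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  ma <- apply(do.call(rbind, group_a), 2, median)
  mb <- apply(do.call(rbind, group_b), 2, median)
  delta <- (ma - mb) / mb
  out <- data.frame(parameter = names(ma), median_a = unname(ma),
                    median_b = unname(mb), delta = unname(delta))
  out <- out[abs(out$delta) > threshold, , drop = FALSE]
  out[order(-abs(out$delta)), , drop = FALSE]
}

#' Run a full population study
#'
#' Samples scalings, simulates every member under both protocols and
#' calibrates in the requested modes.
#'
#' @param params environment-adapted baseline parameters.
#' @param n population size.
#' @param seed sampling seed.
#' @param ranges range table (defaults to the packaged experimental ranges).
#' @param modes calibration modes to evaluate.
#' @param duration,keep,record_step forwarded to [simulate_member()].
#' @param progress print one line per member.
#' @return list with `members` (after AP_CaTr-mode status assignment),
#'   `status` (matrix mode x member of statuses), `counts` (accepted per
#'   mode), `n`, `seed`.
#' @export
run_population <- function(params, n, seed = 1, ranges = default_range_table(),
                           modes = c("AP_CaTr", "AP_only", "CaTr_only"),
                           duration = 800, keep = 300, record_step = 0.005,
                           progress = FALSE) {
  scalings <- sample_scalings(n, seed = seed)
  members <- vector("list", n)
  for (i in seq_len(n)) {
    members[[i]] <- simulate_member(params, scalings[[i]],
                                    id = sprintf("m%04d", i),
                                    duration = duration, keep = keep,
                                    record_step = record_step, ranges = ranges)
    # biomarker summaries are small; traces are dropped as we go
    if (progress)
      message(sprintf("member %d/%d: %s", i, n, members[[i]]$status))
  }
  status <- sapply(modes, function(md)
    vapply(calibrate(members, ranges, md), `[[`, character(1), "status"))
  if (is.null(dim(status))) status <- matrix(status, nrow = 1, dimnames = list(NULL, modes))
  counts <- colSums(status == "accepted")
  list(members = members, status = status, counts = counts, n = n, seed = seed)
}
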