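# Pore-block drug modeling and rule-based phenotype classification.

#' Residual current fraction under the pore-block drug model
#'
#' residual = 1 / (1 + (conc/IC50)^hill); the fraction multiplies the
#' targeted current's maximal conductance.
#'
#' @param conc drug concentration, uM (>= 0).
#' @param ic50 half-maximal inhibitory concentration, uM (> 0).
#' @param hill Hill coefficient (> 0).
#' @return fraction in (0, 1], monotone non-increasing in `conc`.
#' @export
residual_fraction <- function(conc, ic50, hill) {
  if (any(conc < 0)) stop("concentration must be >= 0")
  if (any(ic50 <= 0) || any(hill <= 0)) stop("ic50 and hill must be > 0")
  1 / (1 + (conc / ic50)^hill)
}

#' Read a drug specification from YAML
#'
#' Schema: `name`; `channels:` map current -> `{ic50_um, hill}`;
#' `doses_um:` increasing dose list (labelled D1..Dn); optional
#' `eftpc_max_um` and per-current `overrides:` residual fractions.
#'
#' @param path YAML file.
#' @return a `cm_drug` object.
#' @export
read_drug <- function(path) {
  raw <- yaml::read_yaml(path)
  new_drug(raw$name, raw$channels, unlist(raw$doses_um),
           eftpc_max = raw$eftpc_max_um,
           overrides = if (!is.null(raw$overrides)) unlist(raw$overrides) else NULL)
}

#' Construct a drug specification
#'
#' @param name drug name.
#' @param channels named list: current -> list(ic50_um, hill).
#' @param doses_um strictly increasing positive doses, uM.
#' @param eftpc_max maximal effective free therapeutic plasma concentration,
#'   uM (optional; anchors ad-hoc dose extensions).
#' @param overrides named residual-fraction overrides (current -> fraction).
#' @return a `cm_drug`.
#' @export
new_drug <- function(name, channels, doses_um, eftpc_max = NULL, overrides = NULL) {
  stopifnot(length(doses_um) >= 1, all(doses_um > 0), !is.unsorted(doses_um, strictly = TRUE))
  unknown <- setdiff(names(channels), names(current_conductance_map()))
  if (length(unknown)) stop("unknown current(s) in drug spec: ",
                            paste(unknown, collapse = ", "))
  for (ch in channels) {
    if (ch$ic50_um <= 0 || ch$hill <= 0) stop("IC50 and hill must be > 0")
  }
  if (!is.null(overrides)) {
    if (any(overrides <= 0 | overrides > 1)) stop("overrides must lie in (0, 1]")
    unknown <- setdiff(names(overrides), names(channels))
    if (length(unknown)) stop("override for untargeted current: ",
                              paste(unknown, collapse = ", "))
  }
  structure(list(name = name, channels = channels, doses_um = doses_um,
                 eftpc_max = eftpc_max, overrides = overrides),
            class = "cm_drug")
}

#' The packaged drug specifications
#'
#' IC50/Hill tables for astemizole, bepridil, diltiazem, dofetilide and
#' ibutilide. These files are synthetic reconstructions anchored to printed
#' facts (see the file headers and the methods vignette); they are editable
#' inputs, not hard-coded constants.
#'
#' @param name drug name (lower case).
#' @return a `cm_drug`.
#' @export
default_drug <- function(name) {
  path <- system.file("extdata", "drugs",
                      paste0(tolower(name), "_synthetic.yaml"), package = "ipscpop")
  if (!nzchar(path)) stop("no packaged drug spec for ", name)
  read_drug(path)
}

#' Apply a drug at a dose to a parameter set
#'
#' Multiplies each targeted current's maximal conductance by its pore-block
#' residual fraction (or an explicit override). Pure function; dose 0 is the
#' identity.
#'
#' @param params a `cm_parameters` object.
#' @param drug a `cm_drug`.
#' @param dose concentration in uM; must be 0, one of the spec's doses, or
#'   `ad_hoc = TRUE`.
#' @param ad_hoc allow doses outside the spec's list (for dose-extension
#'   experiments anchored to EFTPC_max).
#' @return a new `cm_parameters` object.
#' @export
apply_drug <- function(params, drug, dose, ad_hoc = FALSE) {
  stopifnot(inherits(drug, "cm_drug"), dose >= 0)
  if (dose == 0) return(params)
  if (!ad_hoc && !any(abs(drug$doses_um - dose) < 1e-12))
    stop("dose ", dose, " uM is not in the spec for ", drug$name,
         " (use ad_hoc = TRUE for extensions)")
  res <- vapply(names(drug$channels), function(cur) {
    if (!is.null(drug$overrides) && cur %in% names(drug$overrides))
      drug$overrides[[cur]]
    else residual_fraction(dose, drug$channels[[cur]]$ic50_um,
                           drug$channels[[cur]]$hill)
  }, numeric(1))
  block_currents(params, res)
}

#' Override a drug's blocking action on one channel
#'
#' Returns a copy of the drug with a fixed residual fraction on the named
#' current only (e.g. halving or removing an I_CaL block while preserving the
#' other channel blocks).
#'
#' @param drug a `cm_drug`.
#' @param current targeted current name (must be in the spec).
#' @param residual fraction in (0, 1].
#' @return a `cm_drug`.
#' @export
modulate_channel_block <- function(drug, current, residual) {
  stopifnot(inherits(drug, "cm_drug"))
  if (!current %in% names(drug$channels))
    stop("drug ", drug$name, " does not target ", current)
  if (residual <= 0 || residual > 1) stop("residual must lie in (0, 1]")
  ov <- drug$overrides
  if (is.null(ov)) ov <- numeric(0)
  ov[current] <- residual
  drug$overrides <- ov
  drug
}

# local maxima with a simple two-sided prominence floor
.local_maxima <- function(v, prominence = 1) {
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    # walk left/right to the nearest sample at least as high; valley depth
    l <- i - 1; lmin <- v[i]
    while (l >= 1 && v[l] < v[i]) { lmin <- min(lmin, v[l]); l <- l - 1 }
    r <- i + 1; rmin <- v[i]
    while (r <= n && v[r] < v[i]) { rmin <- min(rmin, v[r]); r <- r + 1 }
    keep[k] <- (v[i] - max(lmin, rmin)) >= prominence
  }
  cand[keep]
}

#' Classify the arrhythmia phenotype of a trace
#'
#' Detectors follow the study's rules: early afterdepolarizations are extra
#' peaks above -55 mV between two consecutive AP upstrokes (with a 1 mV
#' prominence floor against solver ripple); repolarization failure is a
#' stable (max |dVm/dt| < 0.1 V/s) potential above -40 mV over the last 15 s;
#' irregular rhythm is a consecutive cycle-length change greater than 150%;
#' residual activity means excursion peaks between -40 and 0 mV; quiescence
#' means the last-15-s average potential below -40 mV with no suprathreshold
#' peaks. The primary label follows the fixed precedence
#' RA > Q > RESAC > IRR > OK; a spontaneous rate above 2 Hz sets the tachy
#' flag alongside.
#'
#' @param trace a `cm_trace` spanning the full drug window.
#' @param ead_level extra-peak threshold, mV.
#' @param ead_prominence prominence floor, mV.
#' @return a `cm_phenotype`: list with `primary` and detector details.
#' @export
classify_phenotype <- function(trace, ead_level = -55, ead_prominence = 1) {
  stopifnot(inherits(trace, "cm_trace"))
  span <- max(trace$time) - min(trace$time)
  if (span < 15) stop("trace must span at least 15 s")
  t_end <- max(trace$time)
  last15 <- trace$time >= t_end - 15
  vm15 <- trace$vm[last15]

  acts <- detect_upstrokes(trace)
  # all suprathreshold excursion peaks in the last 15 s, with no floor
  tail_tr <- trace_window(trace, t_end - 15, t_end)
  peaks15 <- .excursion_peaks(tail_tr)

  repol_failure <- all(vm15 > -40) && max(abs(trace$dvdt[last15])) < 0.1

  # EADs: interposed maxima between the AP peak of one beat and the next
  # upstroke
  ead_count <- 0L
  if (length(acts) >= 2) {
    for (i in seq_len(length(acts) - 1)) {
      sel <- which(trace$time >= acts[i] & trace$time < acts[i + 1])
      if (length(sel) < 5) next
      vseg <- trace$vm[sel]
      ipk <- which.max(vseg)
      post <- vseg[ipk:length(vseg)]
      mx <- .local_maxima(post, prominence = ead_prominence)
      ead_count <- ead_count + sum(post[mx] > ead_level)
    }
  }

  cls <- diff(acts)
  irregular <- length(cls) >= 2 &&
    any(abs(diff(cls)) / cls[-length(cls)] > 1.5)

  acts30 <- acts[acts >= t_end - 30]
  tachy <- length(acts30) / 30 > 2

  quiescent15 <- (!length(peaks15) || max(peaks15) < -40) && mean(vm15) < -40
  resac15 <- length(peaks15) > 0 && max(peaks15) < 0 && max(peaks15) >= -40

  primary <- if (ead_count > 0 || repol_failure) "RA"
    else if (quiescent15) "Q"
    else if (resac15) "RESAC"
    else if (irregular) "IRR"
    else "OK"

  structure(list(primary = primary, ead_count = ead_count,
                 repol_failure = repol_failure, irregular = irregular,
                 tachy = tachy, n_upstrokes = length(acts),
                 peaks_last15 = peaks15),
            class = "cm_phenotype")
}

# peaks of all contiguous excursions above (MDP + 10% amplitude); no peak floor
.excursion_peaks <- function(trace) {
  vm <- trace$vm
  if (!length(vm)) return(numeric(0))
  mdp <- min(vm); amp <- max(vm) - mdp
  if (amp < 1) return(numeric(0))
  thr <- mdp + 0.1 * amp
  above <- vm > thr
  d <- diff(c(FALSE, above))
  starts <- which(d == 1); ends <- which(diff(c(above, FALSE)) == -1)
  vapply(seq_along(starts), function(k) max(vm[starts[k]:ends[k]]), numeric(1))
}

#' @export
print.cm_phenotype <- function(x, ...) {
  cat(sprintf("<cm_phenotype> %s (EADs %d, repol failure %s, IRR %s, tachy %s)\n",
              x$primary, x$ead_count, x$repol_failure, x$irregular, x$tachy))
  invisible(x)
}

.phenotype_levels <- c("OK", "Q", "RA", "IRR", "RESAC")

#' Run an in silico drug trial over a population
#'
#' For each dose, every member is simulated 400 s nonpaced from its control
#' steady state under the drugged parameters, then classified. Members whose
#' integration fails are counted in a distinct `failed` column, never
#' dropped.
#'
#' @param population list of members: each a list with `id`, `params`
#'   (scaled, environment-adapted `cm_parameters`) and `steady_state`.
#' @param drug a `cm_drug`.
#' @param doses doses to sweep (defaults to the spec's D1..Dn).
#' @param duration seconds per run.
#' @param record_step sampling step (s).
#' @param with_biomarkers also summarize last-20-beat biomarkers of
#'   still-beating members.
#' @param ad_hoc allow off-spec doses.
#' @param progress print progress lines.
#' @return list with `counts` (data.frame dose x OK/Q/RA/IRR/RESAC/failed +
#'   tachy), `labels` (dose x member matrix) and optionally `biomarkers`.
#' @export
run_population_trial <- function(population, drug, doses = drug$doses_um,
                                 duration = 400, record_step = 0.005,
                                 with_biomarkers = FALSE, ad_hoc = FALSE,
                                 progress = FALSE) {
  ids <- vapply(population, `[[`, character(1), "id")
  labels <- matrix(NA_character_, nrow = length(doses), ncol = length(population),
                   dimnames = list(paste0("D", seq_along(doses)), ids))
  counts <- data.frame(dose_um = doses,
                       OK = 0L, Q = 0L, RA = 0L, IRR = 0L, RESAC = 0L,
                       failed = 0L, tachy = 0L)
  bmk <- list()
  for (d in seq_along(doses)) {
    rows <- list()
    for (m in seq_along(population)) {
      mem <- population[[m]]
      pd <- apply_drug(mem$params, drug, doses[d], ad_hoc = ad_hoc)
      tr <- tryCatch(suppressWarnings(
                       run_drug_trial(pd, mem$steady_state, duration = duration,
                                      record_step = record_step)),
                     error = function(e) e)
      if (inherits(tr, "error")) {
        counts$failed[d] <- counts$failed[d] + 1L
        labels[d, m] <- "failed"
      } else {
        ph <- classify_phenotype(tr)
        labels[d, m] <- ph$primary
        counts[[ph$primary]][d] <- counts[[ph$primary]][d] + 1L
        if (ph$tachy) counts$tachy[d] <- counts$tachy[d] + 1L
        if (with_biomarkers && ph$primary %in% c("OK", "IRR")) {
          bm <- summarize_biomarkers(tr)
          if (!is.null(bm))
            rows[[length(rows) + 1]] <- data.frame(
              id = mem$id, dose_um = doses[d],
              APD90 = biomarker_value(bm, "APD90"),
              CTD90 = biomarker_value(bm, "CTD90"),
              AP_CL = biomarker_value(bm, "AP_CL"))
        }
      }
      if (progress)
        message(sprintf("dose %g uM member %s: %s", doses[d], mem$id, labels[d, m]))
    }
    if (with_biomarkers) bmk[[d]] <- do.call(rbind, rows)
  }
  out <- list(counts = counts, labels = labels)
  if (with_biomarkers) out$biomarkers <- do.call(rbind, bmk)
  out
}

#' Write a drug-trial count table as CSV
#' @param trial result of [run_population_trial()].
#' @param path output file.
#' @export
write_trial_table <- function(trial, path) {
  write.csv(trial$counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
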