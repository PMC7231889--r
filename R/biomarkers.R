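# Beat segmentation and AP / Ca-transient biomarker extraction.
#
# Durations are reported in ms, potentials in mV, upstroke velocity in V/s and
# CaTr amplitude in nM. Level crossings are located by linear interpolation
# between samples, so on piecewise-linear traces they are exact.

# linear-interpolated time of first downward crossing of `level` in (tt, vv)
# starting at index i0; NA if never crossed.
.cross_down <- function(tt, vv, level, i0 = 1) {
  n <- length(vv)
  if (i0 >= n) return(NA_real_)
  idx <- which(vv[(i0 + 1):n] < level & vv[i0:(n - 1)] >= level)
  if (!length(idx)) return(NA_real_)
  i <- i0 + idx[1] - 1
  t1 <- tt[i]; t2 <- tt[i + 1]; v1 <- vv[i]; v2 <- vv[i + 1]
  if (v1 == v2) return(t2)
  t1 + (level - v1) * (t2 - t1) / (v2 - v1)
}

# first upward crossing
.cross_up <- function(tt, vv, level, i0 = 1) {
  n <- length(vv)
  if (i0 >= n) return(NA_real_)
  idx <- which(vv[(i0 + 1):n] > level & vv[i0:(n - 1)] <= level)
  if (!length(idx)) return(NA_real_)
  i <- i0 + idx[1] - 1
  t1 <- tt[i]; t2 <- tt[i + 1]; v1 <- vv[i]; v2 <- vv[i + 1]
  if (v1 == v2) return(t2)
  t1 + (level - v1) * (t2 - t1) / (v2 - v1)
}

#' Segment a trace into complete beats
#'
#' One segment per activation followed by a complete repolarization; windows
#' span MDP-to-MDP and the last incomplete beat is dropped. The Ca-transient
#' onset of a beat is the diastolic Cai minimum preceding the Cai peak
#' associated with that beat.
#'
#' @param trace a `cm_trace`.
#' @param activations sorted activation times from [detect_upstrokes()];
#'   computed if missing.
#' @return list of beat segments (possibly empty), each a list with
#'   `activation_time`, `t_start`, `t_end`, index range, `MDP_pre`,
#'   `MDP_post`, `peak_Vm`, `peak_time`, `peak_Cai`, `Cai_onset_time`,
#'   `Cai_diastolic`.
#' @export
segment_beats <- function(trace, activations = detect_upstrokes(trace)) {
  stopifnot(inherits(trace, "cm_trace"))
  if (length(activations) < 2) return(list())
  tt <- trace$time; vm <- trace$vm; cai <- trace$cai
  segs <- vector("list", length(activations) - 1)
  for (i in seq_len(length(activations) - 1)) {
    a <- activations[i]
    prev <- if (i == 1) tt[1] else activations[i - 1]
    # open intervals: the activation sample itself can sit at the upstroke
    # foot (Vm == MDP) and must not be taken as the window boundary
    ipre <- which(tt > prev & tt <= a)
    if (!length(ipre)) ipre <- which(tt <= a)  # activation at the first sample
    i_start <- ipre[which.min(vm[ipre])]
    ipost <- which(tt >= a & tt < activations[i + 1])
    vpost <- vm[ipost]
    i_end <- ipost[max(which(vpost == min(vpost)))]  # last MDP sample (flat-tie safe)
    win <- i_start:i_end
    ipk <- win[which.max(vm[win])]
    ia <- which(tt >= a)[1]
    iac <- win[win >= ia]
    icp <- iac[which.max(cai[iac])]   # Ca peak associated with this beat
    # diastolic level: Cai minimum preceding the peak within the window
    idia <- i_start:icp
    ca_dia <- min(cai[idia])
    # onset: foot of the rapid rise = last upward crossing of the
    # diastolic + 10%-amplitude level before the peak (linear interpolation)
    lev <- ca_dia + 0.1 * (cai[icp] - ca_dia)
    kk <- idia[-length(idia)]
    up <- kk[cai[kk] <= lev & cai[kk + 1] > lev]
    onset <- if (length(up)) {
      k <- up[length(up)]
      if (cai[k + 1] == cai[k]) tt[k]
      else tt[k] + (lev - cai[k]) * (tt[k + 1] - tt[k]) / (cai[k + 1] - cai[k])
    } else tt[idia[which.min(cai[idia])]]
    segs[[i]] <- list(
      activation_time = a, t_start = tt[i_start], t_end = tt[i_end],
      i_start = i_start, i_end = i_end,
      MDP_pre = vm[i_start], MDP_post = vm[i_end],
      peak_Vm = vm[ipk], peak_time = tt[ipk],
      peak_Cai = cai[icp], peak_Cai_time = tt[icp],
      Cai_onset_time = onset, Cai_diastolic = ca_dia
    )
  }
  segs
}

#' Per-beat action-potential biomarkers
#'
#' Amplitude is peak_Vm minus the following MDP; APDx is the time from the
#' activation (maximal dVm/dt) to the first downward crossing of
#' peak - x% * amplitude; the triangulation ratio is (t40 - t30)/(t80 - t70).
#' A repolarization that never reaches the 90% level yields `NA` durations
#' (feeding the repolarization-failure logic), not an error.
#'
#' @param trace the `cm_trace` the beat was segmented from.
#' @param beat one element of [segment_beats()].
#' @return named numeric vector of per-beat AP biomarkers.
#' @export
ap_biomarkers <- function(trace, beat) {
  tt <- trace$time; vm <- trace$vm
  win <- beat$i_start:beat$i_end
  twin <- tt[win]; vwin <- vm[win]
  amp <- beat$peak_Vm - beat$MDP_post
  ipk <- which.max(vwin)
  apd <- function(x) {
    cr <- .cross_down(twin, vwin, beat$peak_Vm - x / 100 * amp, ipk)
    if (is.na(cr)) NA_real_ else (cr - beat$activation_time) * 1000
  }
  a10 <- apd(10); a30 <- apd(30); a40 <- apd(40); a50 <- apd(50)
  a70 <- apd(70); a80 <- apd(80); a90 <- apd(90)
  dvdt_win <- trace$dvdt[beat$i_start:which(tt == beat$peak_time)[1]]
  c(APD10 = a10, APD30 = a30, APD50 = a50, APD90 = a90,
    AP_Tri90_30 = a90 - a30,
    AP_Tri_ratio = if (anyNA(c(a30, a40, a70, a80))) NA_real_
                   else (a40 - a30) / (a80 - a70),
    APA = amp, MDP = beat$MDP_post, AP_peak = beat$peak_Vm,
    dVdt_max = max(dvdt_win))
}

#' Per-beat calcium-transient biomarkers
#'
#' Amplitude (nM) is peak minus diastolic Cai; CTDx runs from the CaTr onset
#' to the decay crossing of peak - x% * amplitude; tRise0,peak is the
#' onset-to-peak time. Rise/decay times relative to the 10/50/90% levels are
#' also reported (tRise10,peak; tDecay90,10 etc).
#'
#' @inheritParams ap_biomarkers
#' @return named numeric vector of per-beat CaTr biomarkers.
#' @export
catr_biomarkers <- function(trace, beat) {
  tt <- trace$time; cai <- trace$cai
  win <- beat$i_start:beat$i_end
  twin <- tt[win]; cwin <- cai[win]
  amp <- beat$peak_Cai - beat$Cai_diastolic
  icp <- which(twin == beat$peak_Cai_time)[1]
  ion <- max(which(twin <= beat$Cai_onset_time))
  lev <- function(x) beat$Cai_diastolic + x / 100 * amp
  rise <- function(x) .cross_up(twin, cwin, lev(x), ion)
  fall <- function(x) .cross_down(twin, cwin, lev(x), icp)
  ctd <- function(x) {
    cr <- fall(100 - x)   # x% of decay => level at (100 - x)% of amplitude
    if (is.na(cr)) NA_real_ else (cr - beat$Cai_onset_time) * 1000
  }
  r10 <- rise(10); r50 <- rise(50); r90 <- rise(90)
  d90 <- fall(90); d10 <- fall(10)
  c(CTD30 = ctd(30), CTD50 = ctd(50), CTD90 = ctd(90),
    CaTr_Tri90_30 = ctd(90) - ctd(30),
    CaTr_tRise0peak = (beat$peak_Cai_time - beat$Cai_onset_time) * 1000,
    CaTr_tRise10_50 = (r50 - r10) * 1000,
    CaTr_tRise10_90 = (r90 - r10) * 1000,
    CaTr_tRise10_peak = (beat$peak_Cai_time - r10) * 1000,
    CaTr_tDecay90_10 = (d10 - d90) * 1000,
    CaTr_amplitude = amp * 1e6,
    CaTr_diastolic = beat$Cai_diastolic * 1e6)
}

.biomarker_names <- c(
  "AP_CL", "APD10", "APD30", "APD50", "APD90", "AP_Tri90_30", "AP_Tri_ratio",
  "APA", "MDP", "AP_peak", "dVdt_max",
  "CaTr_CL", "CTD30", "CTD50", "CTD90", "CaTr_Tri90_30", "CaTr_tRise0peak",
  "CaTr_tRise10_50", "CaTr_tRise10_90", "CaTr_tRise10_peak",
  "CaTr_tDecay90_10", "CaTr_amplitude", "CaTr_diastolic"
)

#' Summarize a trace into steady-state biomarkers
#'
#' Computes every per-beat AP and CaTr biomarker over the last
#' `min(n_beats, available)` complete beats and reduces them to mean and SD.
#' AP cycle length is the interval between consecutive activation times,
#' CaTr cycle length between consecutive CaTr onsets. A trace without a
#' complete beat yields `NULL` (quiescent marker), not an exception.
#'
#' @param trace a `cm_trace`.
#' @param n_beats number of trailing beats to average (20 in the study
#'   protocol).
#' @return a `cm_biomarkers` object (list with `table` data.frame of
#'   biomarker/mean/sd and `n_beats`), or `NULL` when no complete beat exists.
#' @export
summarize_biomarkers <- function(trace, n_beats = 20) {
  acts <- detect_upstrokes(trace)
  segs <- segment_beats(trace, acts)
  if (!length(segs)) return(NULL)
  use <- segs[max(1, length(segs) - n_beats + 1):length(segs)]
  per <- t(vapply(use, function(b)
    c(ap_biomarkers(trace, b), catr_biomarkers(trace, b)),
    numeric(21)))
  aidx <- match(vapply(use, `[[`, numeric(1), "activation_time"), acts)
  acl <- ifelse(aidx < length(acts),
                (acts[aidx + 1] - acts[aidx]) * 1000, NA_real_)
  onsets <- vapply(use, `[[`, numeric(1), "Cai_onset_time")
  ccl <- c(diff(onsets) * 1000, NA_real_)
  per <- cbind(AP_CL = acl, per[, , drop = FALSE], CaTr_CL = ccl)
  mn <- apply(per, 2, function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
  sdv <- apply(per, 2, function(x) if (sum(!is.na(x)) < 2) 0 else sd(x, na.rm = TRUE))
  tab <- data.frame(biomarker = .biomarker_names,
                    mean = unname(mn[.biomarker_names]),
                    sd = unname(sdv[.biomarker_names]))
  structure(list(table = tab, n_beats = length(use)), class = "cm_biomarkers")
}

#' @export
print.cm_biomarkers <- function(x, ...) {
  cat(sprintf("<cm_biomarkers> over %d beats\n", x$n_beats))
  tab <- x$table
  tab$mean <- signif(tab$mean, 5); tab$sd <- signif(tab$sd, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Extract one biomarker mean (and SD) from a summary
#' @param bm a `cm_biomarkers` object.
#' @param name biomarker name.
#' @param what "mean" or "sd".
#' @return numeric scalar.
#' @export
biomarker_value <- function(bm, name, what = "mean") {
  if (is.null(bm)) return(NA_real_)
  i <- match(name, bm$table$biomarker)
  if (is.na(i)) stop("unknown biomarker: ", name)
  bm$table[[what]][i]
}

#' Write biomarker summaries as a CSV table
#'
#' One row per trace, columns `<biomarker>_mean` / `<biomarker>_sd` in a
#' bit-stable column order, plus `n_beats` and any provenance columns given.
#'
#' @param bms named list of `cm_biomarkers` (NULL entries allowed: quiescent).
#' @param path output file.
#' @param extra optional data.frame of provenance columns (one row per trace).
#' @export
write_biomarker_table <- function(bms, path, extra = NULL) {
  rows <- lapply(names(bms), function(id) {
    bm <- bms[[id]]
    v <- setNames(rep(NA_real_, 2 * length(.biomarker_names)),
                  c(rbind(paste0(.biomarker_names, "_mean"),
                          paste0(.biomarker_names, "_sd"))))
    nb <- 0L
    if (!is.null(bm)) {
      v[paste0(bm$table$biomarker, "_mean")] <- bm$table$mean
      v[paste0(bm$table$biomarker, "_sd")] <- bm$table$sd
      nb <- bm$n_beats
    }
    cbind(data.frame(id = id, n_beats = nb), as.data.frame(as.list(v)))
  })
  df <- do.call(rbind, rows)
  if (!is.null(extra)) df <- cbind(df, extra)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
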