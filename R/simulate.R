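# Stiff initial-value integration of the cell model under the study protocols.

#' Simulation protocol
#'
#' @param mode "nonpaced" (spontaneous activity) or "paced".
#' @param pacing_rate Hz; required when paced.
#' @param stim_amplitude rectangular stimulus amplitude, A/F (default twice
#'   the baseline diastolic threshold, determined once by bisection).
#' @param stim_duration stimulus pulse duration, seconds.
#' @param duration total simulated time, seconds.
#' @param record_step output sampling step, seconds.
#' @param keep length of the trailing window kept at full resolution,
#'   seconds (`Inf` keeps the whole run). Earlier output is thinned; beat
#'   analysis uses the kept window.
#' @return a `cm_protocol` object.
#' @export
protocol <- function(mode = c("nonpaced", "paced"), pacing_rate = NULL,
                     stim_amplitude = 10, stim_duration = 0.005,
                     duration = 800, record_step = 0.002, keep = Inf) {
  mode <- match.arg(mode)
  if (duration < 0) stop("duration must be >= 0")
  if (record_step <= 0) stop("record_step must be > 0")
  if (mode == "paced") {
    if (is.null(pacing_rate) || pacing_rate <= 0)
      stop("paced protocols require pacing_rate > 0")
  } else pacing_rate <- NA_real_
  structure(list(mode = mode, pacing_rate = pacing_rate,
                 stim_amplitude = stim_amplitude, stim_duration = stim_duration,
                 duration = duration, record_step = record_step, keep = keep),
            class = "cm_protocol")
}

.default_rtol <- 1e-7

.default_atol <- function() {
  typ <- c(Vm = 0.1, Ca_SR = 0.1, Cai = 1e-4, Nai = 10)
  a <- setNames(rep(1e-8, length(.state_names)), .state_names)  # gates
  a[names(typ)] <- pmax(typ * 1e-7, 1e-12)
  a
}

#' Integrate the cell model under a protocol
#'
#' Solves the model ODEs with the stiff lsoda solver (compiled right-hand
#' side). When paced, a rectangular current pulse is applied at the pacing
#' rate and the integration is restarted at every pulse edge so the solver
#' never steps across the discontinuity. Output is sampled on the record
#' grid; `final_state` is the exact solver state at end time.
#'
#' @param params a `cm_parameters` object.
#' @param initial named state vector (see [state_names()]).
#' @param proto a `cm_protocol` object.
#' @param rtol,atol solver tolerances (atol per state).
#' @param metadata free-form provenance list stored on the trace.
#' @return a `cm_trace`: list with `time` (s), `vm` (mV), `cai` (mM),
#'   `dvdt` (V/s), `protocol`, `final_state`, `metadata`.
#' @export
run_simulation <- function(params, initial, proto,
                           rtol = .default_rtol, atol = .default_atol(),
                           metadata = list()) {
  stopifnot(inherits(params, "cm_parameters"), inherits(proto, "cm_protocol"))
  initial <- validate_state(initial)
  if (proto$duration == 0)
    return(new_trace(0, initial[["Vm"]] * 1000, initial[["Cai"]],
                     dvdt = 0, proto, initial, metadata))
  t_keep <- max(0, proto$duration - proto$keep)
  grid <- seq(0, proto$duration, by = proto$record_step)
  if (abs(grid[length(grid)] - proto$duration) > 1e-12)
    grid <- c(grid, proto$duration)
  if (t_keep > 0) {
    coarse <- seq(0, t_keep, by = max(proto$record_step, 0.25))
    grid <- sort(unique(c(coarse, grid[grid >= t_keep])))
  }

  paced <- proto$mode == "paced"
  period <- if (paced) 1 / proto$pacing_rate else Inf
  pv <- solver_parms(params,
                     stim_flag = as.numeric(paced),
                     stim_amplitude = proto$stim_amplitude,
                     stim_duration = proto$stim_duration,
                     stim_period = if (paced) period else 1e9,
                     stim_start = 0)

  if (paced) {
    edges <- sort(unique(c(
      seq(0, proto$duration, by = period),
      seq(0, proto$duration, by = period) + proto$stim_duration)))
    edges <- edges[edges > 0 & edges < proto$duration]
    bounds <- unique(c(0, edges, proto$duration))
  } else {
    bounds <- c(0, proto$duration)
  }

  out_list <- vector("list", length(bounds) - 1)
  y <- initial
  for (k in seq_len(length(bounds) - 1)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1]
    times <- unique(c(t0, grid[grid > t0 + 1e-12 & grid < t1 - 1e-12], t1))
    sol <- deSolve::lsoda(y = y, times = times, func = "ipscpop_derivs",
                          parms = pv, dllname = "ipscpop",
                          initfunc = "ipscpop_initmod", nout = length(.current_names),
                          rtol = rtol, atol = atol, maxsteps = 50000)
    istate <- attr(sol, "istate")[1]
    if (is.null(istate) || istate < 0 || nrow(sol) < length(times)) {
      t_fail <- if (nrow(sol) > 0) sol[nrow(sol), 1] else t0
      cond <- structure(class = c("cm_integration_error", "error", "condition"),
                        list(message = sprintf("integration failed at t = %.4f s", t_fail),
                             call = sys.call(-1),
                             time = t_fail,
                             last_state = if (nrow(sol) > 0)
                               setNames(sol[nrow(sol), 1 + seq_along(.state_names)],
                                        .state_names) else y))
      stop(cond)
    }
    y <- setNames(sol[nrow(sol), 1 + seq_along(.state_names)], .state_names)
    out_list[[k]] <- sol[if (k > 1) -1L else TRUE, , drop = FALSE]
  }
  sol <- do.call(rbind, out_list)

  tcol <- sol[, 1]
  keep_rows <- !duplicated(tcol)
  tcol <- tcol[keep_rows]
  vm <- sol[keep_rows, 1 + match("Vm", .state_names)] * 1000
  cai <- sol[keep_rows, 1 + match("Cai", .state_names)]
  curs <- sol[keep_rows, 1 + length(.state_names) + seq_along(.current_names),
              drop = FALSE]
  colnames(curs) <- .current_names
  dvdt <- -(rowSums(curs[, .membrane_currents, drop = FALSE]) - curs[, "I_stim"])
  new_trace(tcol, vm, cai, dvdt, proto, y, metadata)
}

new_trace <- function(time, vm, cai, dvdt, proto, final_state, metadata = list()) {
  stopifnot(length(time) == length(vm), length(vm) == length(cai))
  structure(list(time = as.numeric(time), vm = as.numeric(vm),
                 cai = as.numeric(cai), dvdt = as.numeric(dvdt),
                 protocol = proto, final_state = final_state,
                 metadata = metadata),
            class = "cm_trace")
}

#' @export
print.cm_trace <- function(x, ...) {
  cat(sprintf("<cm_trace> %s, %.1f s, %d samples, Vm [%.1f, %.1f] mV\n",
              x$protocol$mode, diff(range(x$time)), length(x$time),
              min(x$vm), max(x$vm)))
  invisible(x)
}

# Restrict a trace to a time window [t0, t1].
trace_window <- function(trace, t0 = -Inf, t1 = Inf) {
  sel <- trace$time >= t0 & trace$time <= t1
  new_trace(trace$time[sel], trace$vm[sel], trace$cai[sel], trace$dvdt[sel],
            trace$protocol, trace$final_state, trace$metadata)
}

#' Run the model to its steady state
#'
#' Integrates the model for 800 s (default) so biomarkers can be computed in
#' the steady state as the average of the last 20 beats. A model that stops
#' beating is not an error; the quiescent trace is returned and labelled
#' downstream.
#'
#' @param params a `cm_parameters` object.
#' @param proto protocol; defaults to 800 s nonpaced with the trailing 300 s
#'   kept at full resolution.
#' @param initial starting state; defaults to the packaged baseline state for
#'   the parameter set's temperature.
#' @param ... passed to [run_simulation()].
#' @return a `cm_trace`.
#' @export
run_steady_state <- function(params, proto = NULL, initial = NULL, ...) {
  if (is.null(proto))
    proto <- protocol("nonpaced", duration = 800, record_step = 0.002, keep = 300)
  if (is.null(initial)) {
    initial <- if (abs(params$environment$temperature - 37) < 1)
      initial_state("steady_37c") else initial_state("steady_21c")
  }
  run_simulation(params, initial, proto, ...)
}

#' Run a drug trial simulation
#'
#' Integrates drugged parameters nonpaced for 400 s from the control steady
#' state of the same model, recording the whole window for abnormality
#' detection.
#'
#' @param drugged a `cm_parameters` object with drug block applied.
#' @param steady_state the final state of the control steady-state run.
#' @param duration seconds (400 in the study protocol).
#' @param record_step sampling step in seconds.
#' @param ... passed to [run_simulation()].
#' @return a `cm_trace`.
#' @export
run_drug_trial <- function(drugged, steady_state, duration = 400,
                           record_step = 0.005, ...) {
  proto <- protocol("nonpaced", duration = duration, record_step = record_step,
                    keep = Inf)
  run_simulation(drugged, steady_state, proto, ...)
}

#' Detect action-potential upstrokes in a trace
#'
#' A suprathreshold excursion is a contiguous segment with Vm above
#' MDP + 10 percent of the trace's excursion amplitude; the activation time is
#' the argmax of dVm/dt within the segment. Excursions whose peak stays below
#' -40 mV are not counted as upstrokes (they are residual-activity
#' candidates).
#'
#' @param trace a `cm_trace`.
#' @param peak_floor minimal excursion peak (mV) to count as an upstroke.
#' @return numeric vector of activation times (s), sorted, no duplicates.
#' @export
detect_upstrokes <- function(trace, peak_floor = -40) {
  stopifnot(inherits(trace, "cm_trace"))
  vm <- trace$vm; tt <- trace$time
  if (!length(vm)) stop("trace is empty")
  mdp <- min(vm); amp <- max(vm) - mdp
  if (amp < 1) return(numeric(0))  # flat trace
  thr <- mdp + 0.1 * amp
  above <- vm > thr
  d <- diff(c(FALSE, above))
  starts <- which(d == 1); ends <- which(diff(c(above, FALSE)) == -1)
  if (!length(starts)) return(numeric(0))
  dvdt <- trace$dvdt
  if (is.null(dvdt) || !length(dvdt)) dvdt <- c(diff(vm) / diff(tt) / 1000, 0)
  acts <- numeric(0)
  for (k in seq_along(starts)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (max(vm[i0:i1]) < peak_floor) next
    # include the sample preceding the threshold crossing so the upstroke
    # foot is eligible as the dVm/dt argmax
    i0 <- max(i0 - 1, 1)
    imax <- i0 - 1 + which.max(dvdt[i0:i1])
    acts <- c(acts, tt[imax])
  }
  sort(unique(acts))
}

#' Write / read a trace as plain CSV
#'
#' Columns `time`, `vm`, `cai`, `dvdt` at full precision.
#' @param trace a `cm_trace`.
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time = trace$time, vm = trace$vm, cai = trace$cai,
                   dvdt = trace$dvdt)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param proto protocol to attach on read.
#' @export
read_trace <- function(path, proto = protocol("nonpaced", duration = 0)) {
  df <- read.csv(path)
  new_trace(df$time, df$vm, df$cai,
            if ("dvdt" %in% names(df)) df$dvdt else c(diff(df$vm) / diff(df$time) / 1000, 0),
            proto, final_state = NULL)
}
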