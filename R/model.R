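# ODE state layout, current evaluation and the model right-hand side.

.state_names <- c(
  "Vm", "Ca_SR", "Cai", "d", "f1", "f2", "fCa", "Xr1", "Xr2", "Xs",
  "h", "j", "m", "Xf", "q", "r", "Nai", "mL", "hL", "RyRa", "RyRo", "RyRc"
)

.current_names <- c(
  "I_Na", "I_NaL", "I_f", "I_CaL", "I_to", "I_Kr", "I_Ks", "I_K1",
  "I_NCX", "I_NaK", "I_pCa", "I_bNa", "I_bCa", "I_rel", "I_up", "I_leak",
  "I_stim"
)

.membrane_currents <- c("I_Na", "I_NaL", "I_f", "I_CaL", "I_to", "I_Kr",
                        "I_Ks", "I_K1", "I_NCX", "I_NaK", "I_pCa",
                        "I_bNa", "I_bCa")

#' Names and order of the ODE state vector
#'
#' Vm is in volts (model units), gates dimensionless in \[0, 1\], Nai/Cai/Ca_SR
#' in mM.
#' @return character vector of length 22.
#' @export
state_names <- function() .state_names

#' Baseline state vectors
#'
#' `"diastolic"` is a generic near-diastolic starting point from which the
#' baseline model settles into stable spontaneous beating;
#' `"steady_37c"` and `"steady_21c"` are the packaged states after an 800 s
#' pre-run of the baseline model at reference conditions (37 C) and at the
#' optical-recording conditions (21 C, Nao 135 / Ko 5.4 / Cao 1.33 mM).
#'
#' @param which one of "diastolic", "steady_37c", "steady_21c".
#' @return named numeric state vector.
#' @export
initial_state <- function(which = c("steady_37c", "diastolic", "steady_21c")) {
  which <- match.arg(which)
  file <- system.file("extdata", paste0("state_", which, ".csv"), package = "ipscpop")
  if (!nzchar(file) || !file.exists(file))
    stop("packaged state '", which, "' not found")
  tab <- read.csv(file, stringsAsFactors = FALSE)
  setNames(tab$value, tab$state)[.state_names]
}

validate_state <- function(state) {
  if (length(state) != length(.state_names))
    stop("state must have ", length(.state_names), " entries")
  if (is.null(names(state))) names(state) <- .state_names
  bad <- names(state)[!is.finite(state)]
  if (length(bad)) stop("non-finite state component: ", paste(bad, collapse = ", "))
  gates <- setdiff(.state_names, c("Vm", "Cai", "Ca_SR", "Nai"))
  if (any(state[gates] < -1e-9 | state[gates] > 1 + 1e-9))
    stop("gating variables must lie in [0, 1]")
  if (any(state[c("Cai", "Ca_SR", "Nai")] <= 0))
    stop("ionic concentrations must be strictly positive")
  state[.state_names]
}

#' Evaluate every membrane current and SR flux at a given state
#'
#' Deterministic, pure evaluation of the 13 membrane currents (A/F), the three
#' SR Ca2+ fluxes (mM/s) and the stimulus current at one state.
#'
#' @param state named numeric state vector (see [state_names()]).
#' @param params a `cm_parameters` object.
#' @param t time in seconds (only relevant for the stimulus).
#' @param stim stimulus amplitude in A/F applied at time `t` (constant).
#' @return named numeric vector of currents.
#' @export
compute_currents <- function(state, params, t = 0, stim = 0) {
  state <- validate_state(state)
  pv <- solver_parms(params, stim_flag = as.numeric(stim != 0),
                     stim_amplitude = stim, stim_duration = Inf,
                     stim_period = Inf, stim_start = 0)
  ans <- .Call(C_cell_eval, as.numeric(state), as.numeric(pv), as.numeric(t))
  setNames(ans[[2]], .current_names)
}

#' Model right-hand side
#'
#' Returns the full state derivative: dVm/dt in V/s equals minus the signed
#' sum of the 13 membrane currents (A/F) plus the stimulus; gate derivatives
#' follow the (x_inf - x)/tau form; Ca2+ is conserved between cytosol and SR
#' up to the volume ratio and instantaneous buffering.
#'
#' @inheritParams compute_currents
#' @return named numeric vector of d(state)/dt.
#' @export
model_rhs <- function(state, params, t = 0, stim = 0) {
  state <- validate_state(state)
  if (!is.finite(stim)) stop("stim must be finite")
  pv <- solver_parms(params, stim_flag = as.numeric(stim != 0),
                     stim_amplitude = stim, stim_duration = Inf,
                     stim_period = Inf, stim_start = 0)
  ans <- .Call(C_cell_eval, as.numeric(state), as.numeric(pv), as.numeric(t))
  setNames(ans[[1]], .state_names)
}

#' Voltage-dependent gate steady states at a clamped potential
#'
#' Utility for probe states: returns the state vector with every gate set to
#' its steady-state value at the given membrane potential (RyR gates at their
#' Cai-dependent steady state).
#'
#' @param vm membrane potential in volts.
#' @param params a `cm_parameters` object.
#' @param concentrations named vector with Nai, Cai, Ca_SR (mM).
#' @return named numeric state vector.
#' @export
steady_gate_state <- function(vm, params,
                              concentrations = c(Nai = 9.5, Cai = 4e-5, Ca_SR = 0.32)) {
  st <- setNames(rep(0.5, length(.state_names)), .state_names)
  st["Vm"] <- vm
  st[names(concentrations)] <- concentrations
  # fixed-point iteration: gate derivative zero <=> x = x_inf; obtain x_inf by
  # solving dx = (x_inf - x)/tau at two probe values of x.
  d0 <- model_rhs(st, params)
  st2 <- st
  gates <- setdiff(.state_names, c("Vm", "Cai", "Ca_SR", "Nai"))
  st2[gates] <- 0.25
  d1 <- model_rhs(st2, params)
  for (g in gates) {
    # dx = (xinf - x)/tau is linear in x: recover xinf from two evaluations
    slope <- (d1[g] - d0[g]) / (st2[g] - st[g])     # = -1/tau
    xinf <- st[g] - d0[g] / slope
    st[g] <- min(1, max(0, xinf))
  }
  st
}
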