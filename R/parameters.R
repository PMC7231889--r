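#' @useDynLib ipscpop, .registration = TRUE
#' @importFrom stats approx median sd setNames runif
#' @importFrom utils read.csv write.csv modifyList packageVersion
NULL

# Names of the 16 conductance/flux scale factors, keyed by current.
.current_conductance <- c(
  I_Na = "g_Na", I_NaL = "g_NaL", I_f = "g_f", I_CaL = "g_CaL", I_to = "g_to",
  I_Kr = "g_Kr", I_Ks = "g_Ks", I_K1 = "g_K1", I_NCX = "k_NCX", I_NaK = "P_NaK",
  I_pCa = "g_PCa", I_bNa = "g_bNa", I_bCa = "g_bCa", I_rel = "g_rel",
  I_up = "V_up", I_leak = "V_leak"
)

# Kinetics-family multipliers applied to gating time constants.
.tau_families <- c("Na_act", "Na_inact", "NaL", "CaL_act", "CaL_inact",
                   "Kr", "Ks", "to", "f", "rel")

# Map from Q10 table entries to tau-multiplier families.
.q10_map <- list(
  I_Na = c("Na_act", "Na_inact"), I_NaL = "NaL", I_CaL = c("CaL_act", "CaL_inact"),
  I_Kr = "Kr", I_Ks = "Ks", I_to = "to", I_f = "f", I_rel = "rel"
)

#' Names of the 22 population-scalable parameters
#'
#' Thirteen maximal conductances/fluxes (I_Na, I_NaL, I_f, I_CaL, I_to, I_Ks,
#' I_Kr, I_K1, I_NCX, I_NaK, I_pCa, I_rel, I_up), the activation and
#' inactivation time constants of I_Na, I_CaL and I_rel, the I_rel adaptation
#' time constant and half-inactivation Ca2+ level, and the SERCA
#' half-saturation constant K_up.
#'
#' @return character vector of length 22, in canonical order.
#' @export
scalable_parameter_names <- function() {
  c("g_Na", "g_NaL", "g_f", "g_CaL", "g_to", "g_Ks", "g_Kr", "g_K1",
    "k_NCX", "P_NaK", "g_PCa", "g_rel", "V_up",
    "tau_m_Na", "tau_h_Na", "tau_d_CaL", "tau_f_CaL",
    "tau_act_rel", "tau_inact_rel", "tau_adapt_rel",
    "Ca_half_rel", "K_up")
}

#' Load the packaged baseline model parameter set
#'
#' Reads the flat YAML parameter file shipped with the package (all model
#' constants, the environment block and the Q10 table) and returns a
#' `cm_parameters` object at reference conditions (37 degrees C).
#'
#' @param path path to a parameter YAML file; default is the packaged baseline.
#' @return a `cm_parameters` object.
#' @export
default_parameters <- function(path = system.file("extdata", "model_parameters.yaml",
                                                  package = "ipscpop")) {
  read_parameters(path)
}

#' Read a model parameter file
#'
#' @param path YAML file with `constants`, `environment` and `q10` sections.
#' @return a `cm_parameters` object.
#' @export
read_parameters <- function(path) {
  raw <- yaml::read_yaml(path)
  for (sec in c("constants", "environment", "q10"))
    if (is.null(raw[[sec]])) stop("parameter file lacks section '", sec, "'")
  env <- do.call(environment_conditions, raw$environment)
  p <- structure(list(
    constants = vapply(raw$constants, as.numeric, numeric(1)),
    environment = env,
    q10 = vapply(raw$q10, as.numeric, numeric(1)),
    tau_q10 = setNames(rep(1, length(.tau_families)), .tau_families),
    tau_scale = setNames(rep(1, length(.tau_families)), .tau_families)
  ), class = "cm_parameters")
  validate_parameters(p)
  p
}

#' Write a parameter set to YAML
#' @param params a `cm_parameters` object.
#' @param path output file.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "cm_parameters"))
  yaml::write_yaml(list(
    environment = unclass(params$environment),
    constants = as.list(params$constants),
    q10 = as.list(params$q10)
  ), path, precision = 15)
  invisible(path)
}

#' Environment conditions (temperature and extracellular concentrations)
#'
#' @param temperature degrees Celsius, in \[0, 45\].
#' @param Nao,Ko,Cao extracellular Na+, K+, Ca2+ in mM (strictly positive).
#' @return an `environment_conditions` object.
#' @export
environment_conditions <- function(temperature = 37, Nao = 151, Ko = 5.4, Cao = 1.8) {
  if (!is.finite(temperature) || temperature < 0 || temperature > 45)
    stop("temperature must lie in [0, 45] degrees C")
  conc <- c(Nao = Nao, Ko = Ko, Cao = Cao)
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("extracellular concentrations must be strictly positive")
  structure(list(temperature = temperature, Nao = Nao, Ko = Ko, Cao = Cao),
            class = "environment_conditions")
}

validate_parameters <- function(params) {
  stopifnot(inherits(params, "cm_parameters"))
  pos <- c(unname(.current_conductance), "Cm", "Vc", "V_SR", "K_up", "Ca_half_rel",
           "tau_act_rel", "tau_inact_rel", "tau_adapt_rel")
  miss <- setdiff(pos, names(params$constants))
  if (length(miss)) stop("missing parameter constants: ", paste(miss, collapse = ", "))
  if (any(params$constants[pos] <= 0))
    stop("conductances, volumes, capacitance and kinetics constants must be > 0")
  if (any(params$q10 <= 0)) stop("Q10 factors must be strictly positive")
  invisible(params)
}

#' Adapt a parameter set to new environment conditions
#'
#' Sets the temperature used by the Nernst potentials and the explicitly
#' temperature-dependent currents (I_NCX, I_NaK), replaces the extracellular
#' concentrations, and rescales every gating time constant in family i by
#' Q10_i^((37 - T)/10), so cooling slows all rescaled kinetics. Returns a new
#' object; the input is untouched.
#'
#' @param params a `cm_parameters` object.
#' @param env an `environment_conditions` object.
#' @return a new `cm_parameters` object.
#' @export
adapt_to_environment <- function(params, env) {
  stopifnot(inherits(params, "cm_parameters"))
  if (!inherits(env, "environment_conditions")) env <- do.call(environment_conditions, env)
  out <- params
  out$environment <- env
  fac <- (37 - env$temperature) / 10
  for (cur in names(.q10_map)) {
    q <- params$q10[[cur]]
    if (is.null(q) || is.na(q)) q <- 1
    out$tau_q10[.q10_map[[cur]]] <- q^fac
  }
  out
}

#' Apply a 22-entry population scaling vector
#'
#' Multiplies each population-scalable entry by its dimensionless factor;
#' conductance entries scale the maximal conductance, kinetics entries scale
#' the corresponding time constants (or K_up / the I_rel half-inactivation
#' level). Pure function.
#'
#' @param params a `cm_parameters` object.
#' @param scaling named numeric vector; names must be exactly
#'   `scalable_parameter_names()`, values in \[0.5, 2\].
#' @param low,high admissible factor range.
#' @return a new `cm_parameters` object.
#' @export
apply_scaling <- function(params, scaling, low = 0.5, high = 2.0) {
  stopifnot(inherits(params, "cm_parameters"))
  want <- scalable_parameter_names()
  if (length(scaling) != length(want) || is.null(names(scaling)) ||
      !setequal(names(scaling), want))
    stop("scaling must have exactly the 22 named entries of scalable_parameter_names()")
  scaling <- scaling[want]
  bad <- names(scaling)[scaling < low | scaling > high | !is.finite(scaling)]
  if (length(bad))
    stop("scaling factor out of [", low, ", ", high, "] for: ",
         paste(bad, collapse = ", "))
  out <- params
  cond <- c("g_Na", "g_NaL", "g_f", "g_CaL", "g_to", "g_Ks", "g_Kr", "g_K1",
            "k_NCX", "P_NaK", "g_PCa", "g_rel", "V_up")
  out$constants[cond] <- out$constants[cond] * scaling[cond]
  direct <- c("tau_act_rel", "tau_inact_rel", "tau_adapt_rel", "Ca_half_rel", "K_up")
  out$constants[direct] <- out$constants[direct] * scaling[direct]
  out$tau_scale["Na_act"] <- out$tau_scale["Na_act"] * scaling[["tau_m_Na"]]
  out$tau_scale["Na_inact"] <- out$tau_scale["Na_inact"] * scaling[["tau_h_Na"]]
  out$tau_scale["CaL_act"] <- out$tau_scale["CaL_act"] * scaling[["tau_d_CaL"]]
  out$tau_scale["CaL_inact"] <- out$tau_scale["CaL_inact"] * scaling[["tau_f_CaL"]]
  out
}

#' Block currents by multiplying maximal conductances with residual fractions
#'
#' @param params a `cm_parameters` object.
#' @param residual_fractions named numeric vector/list, names among
#'   `names(current_conductance_map())`, values in \[0, 1\]. A residual of 0.5
#'   halves the current's maximal conductance; an empty map is the identity.
#' @return a new `cm_parameters` object.
#' @export
block_currents <- function(params, residual_fractions = numeric()) {
  stopifnot(inherits(params, "cm_parameters"))
  residual_fractions <- unlist(residual_fractions)
  if (!length(residual_fractions)) return(params)
  unknown <- setdiff(names(residual_fractions), names(.current_conductance))
  if (length(unknown)) stop("unknown current name(s): ", paste(unknown, collapse = ", "))
  if (any(residual_fractions < 0 | residual_fractions > 1))
    stop("residual fractions must lie in [0, 1]")
  out <- params
  keys <- .current_conductance[names(residual_fractions)]
  out$constants[keys] <- out$constants[keys] * residual_fractions
  out
}

#' Map from current names to their maximal-conductance parameters
#' @return named character vector.
#' @export
current_conductance_map <- function() .current_conductance

# Fixed order of the numeric parameter vector consumed by the compiled model.
.solver_parm_names <- c(
  "T_kelvin", "Nao", "Ko", "Cao", "Ki", "Cm", "Vc", "V_SR",
  "g_Na", "g_NaL", "g_f", "fNa_f", "g_CaL", "g_to", "g_Ks", "g_Kr", "g_K1",
  "k_NCX", "P_NaK", "g_PCa", "g_bNa", "g_bCa",
  "g_rel", "V_up", "V_leak", "K_up",
  "RyRa1", "RyRa2", "Ca_half_rel", "RyRohalf", "RyRchalf",
  "tau_adapt_rel", "tau_act_rel", "tau_inact_rel",
  "Buf_C", "Buf_SR", "Kbuf_C", "Kbuf_SR",
  "KmCa", "KmNai", "Ksat", "gamma_NCX", "alpha_NCX",
  "Km_K", "Km_Na", "KPCa", "PkNa", "L0", "Q_Kr", "Vh_hL", "tau_hL",
  "tm_Na_act", "tm_Na_inact", "tm_NaL", "tm_CaL_act", "tm_CaL_inact",
  "tm_Kr", "tm_Ks", "tm_to", "tm_f", "tm_rel",
  "stim_flag", "stim_amplitude", "stim_duration", "stim_period", "stim_start"
)

# Pack a cm_parameters object (plus stimulus settings) into the numeric
# vector expected by the compiled right-hand side.
solver_parms <- function(params, stim_flag = 0, stim_amplitude = 0,
                         stim_duration = 0.005, stim_period = 2, stim_start = 0) {
  k <- params$constants
  env <- params$environment
  tm <- params$tau_q10 * params$tau_scale
  v <- c(
    273.15 + env$temperature, env$Nao, env$Ko, env$Cao, k[["Ki"]],
    k[["Cm"]], k[["Vc"]], k[["V_SR"]],
    k[["g_Na"]], k[["g_NaL"]], k[["g_f"]], k[["fNa_f"]], k[["g_CaL"]],
    k[["g_to"]], k[["g_Ks"]], k[["g_Kr"]], k[["g_K1"]],
    k[["k_NCX"]], k[["P_NaK"]], k[["g_PCa"]], k[["g_bNa"]], k[["g_bCa"]],
    k[["g_rel"]], k[["V_up"]], k[["V_leak"]], k[["K_up"]],
    k[["RyRa1"]], k[["RyRa2"]], k[["Ca_half_rel"]], k[["RyRohalf"]], k[["RyRchalf"]],
    k[["tau_adapt_rel"]], k[["tau_act_rel"]], k[["tau_inact_rel"]],
    k[["Buf_C"]], k[["Buf_SR"]], k[["Kbuf_C"]], k[["Kbuf_SR"]],
    k[["KmCa"]], k[["KmNai"]], k[["Ksat"]], k[["gamma_NCX"]], k[["alpha_NCX"]],
    k[["Km_K"]], k[["Km_Na"]], k[["KPCa"]], k[["PkNa"]], k[["L0"]], k[["Q_Kr"]],
    k[["Vh_hL"]], k[["tau_hL"]],
    tm[["Na_act"]], tm[["Na_inact"]], tm[["NaL"]], tm[["CaL_act"]], tm[["CaL_inact"]],
    tm[["Kr"]], tm[["Ks"]], tm[["to"]], tm[["f"]], tm[["rel"]],
    stim_flag, stim_amplitude, stim_duration, stim_period, stim_start
  )
  setNames(v, .solver_parm_names)
}
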