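# Lazily computed simulation objects shared across test files (helpers are
# loaded once per test session, so expensive steady-state runs happen once).

.sim_cache <- new.env(parent = emptyenv())

cache_get <- function(name, expr) {
  if (!exists(name, envir = .sim_cache, inherits = FALSE))
    assign(name, expr, envir = .sim_cache)
  get(name, envir = .sim_cache, inherits = FALSE)
}

baseline_params <- function() cache_get("p37", default_parameters())

adapted21_params <- function() cache_get("p21", adapt_to_environment(
  baseline_params(), environment_conditions(21, Nao = 135, Ko = 5.4, Cao = 1.33)))

# 800 s spontaneous run of the baseline model at 37 C (the reference protocol)
baseline37_trace <- function() cache_get("tr37", run_steady_state(
  baseline_params(),
  protocol("nonpaced", duration = 800, record_step = 0.001, keep = 60)))

baseline37_biomarkers <- function() cache_get("bm37",
  summarize_biomarkers(baseline37_trace()))

# short densely-sampled continuation for upstroke-velocity measurement
baseline37_fine <- function() cache_get("fine37", run_simulation(
  baseline_params(), baseline37_trace()$final_state,
  protocol("nonpaced", duration = 6, record_step = 2.5e-4)))

# 800 s runs of the environment-adapted model (optical-recording conditions)
adapted21_nonpaced <- function() cache_get("tr21np", run_steady_state(
  adapted21_params(),
  protocol("nonpaced", duration = 800, record_step = 0.002, keep = 300)))

adapted21_paced <- function() cache_get("tr21p", run_simulation(
  adapted21_params(), adapted21_nonpaced()$final_state,
  protocol("paced", pacing_rate = 0.5, duration = 800, record_step = 0.002,
           keep = 300)))

published_baseline_biomarkers <- function() c(
  APA = 102, MDP = -74.9, AP_CL = 1712, dVdt_max = 20.5, APD10 = 87,
  APD30 = 224, APD90 = 390, CaTr_tDecay90_10 = 341, CaTr_CL = 1712,
  CaTr_amplitude = 160)

.default_atol_refined <- function() ipscpop:::.default_atol() / 10
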