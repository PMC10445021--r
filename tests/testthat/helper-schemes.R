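# Shared fixtures built in code.

R_GAS <- gating_constants()$value[1]

markov_scheme <- function(k_open = 2, k_close = 1) {
  two_state_scheme(dwell_law("exponential", rate = k_open),
                   dwell_law("exponential", rate = k_close))
}

gamma_scheme <- function(mean_closed = 0.5, mean_open = 0.2, shape = 2) {
  two_state_scheme(
    dwell_law("gamma", shape = shape, scale = mean_closed / shape),
    dwell_law("gamma", shape = shape, scale = mean_open / shape))
}

all_test_laws <- function() {
  list(
    exponential = dwell_law("exponential", rate = 2),
    gamma = dwell_law("gamma", shape = 2, scale = 0.5),
    stretched_exponential = dwell_law("stretched_exponential",
                                      stretch = 0.5, scale = 1),
    pareto_heavy = dwell_law("pareto", alpha = 0.5, tmin = 0.01),
    pareto_light = dwell_law("pareto", alpha = 2.5, tmin = 0.01))
}

# voltage modulation factor used by the synthetic generator defaults
volt_factor <- function(V, v_half = 0, v_slope = 40) {
  1 / (1 + exp((v_half - V) / v_slope))
}
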