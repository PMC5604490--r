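# Shared fixtures: parameter sets reused across tests.

# published wild-type calibration, 5 mM/5 mM labelled/unlabelled exchange
wt_params <- function(...) carrier_params(...)

# fast-mixing point (weak networks) for stochastic cross-validation:
# transport ~ 1200/s, so 1e5-1e6 jump events cover many barrier crossings
fast_params <- function(...) {
  carrier_params(dE_M = -300, dE_C = -300, dE_S = -300, ...)
}

# single-substrate scenario helper
single_substrate <- function(cyt_M, mat_M) {
  data.frame(name = "substrate", cyt_M = cyt_M, mat_M = mat_M,
             labelled = TRUE, stringsAsFactors = FALSE)
}

# conformational marginal P(c) summed over occupancies
conformational_marginal <- function(result) {
  st <- result$network$states
  as.numeric(tapply(result$P, st$c, sum))
}
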