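# Shared fixtures: fast to build, deterministic.

fsin <- fsin_params()
olm <- olm_params()
cap0 <- calcium_params()

# O-LM start with the FSIN scaling so quantal conversion matches when
# fitting FSIN-generated data (site count and quantal size are fixed
# during fitting and must agree with the data scale).
olm_start_fsin_scale <- function() {
  p <- olm_params()
  p$n_sites <- fsin_params()$n_sites
  p$q <- fsin_params()$q
  p
}

# small, cheap protocol set used by most fitting tests
small_protocols <- function() {
  standard_protocols()[c("train_20hz_6", "train_100hz_6_rec110")]
}

# noise-free per-AP quantal contents for a parameter set
exact_quanta <- function(params, protocols, cap = calcium_params()) {
  lapply(protocols, function(pr)
    simulate_protocol(pr, params, cap)$quanta)
}
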