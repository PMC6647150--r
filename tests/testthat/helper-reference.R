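## Shared fixtures: the excitable-regime reference parameter set and its
## derived objects, computed once per test run.
ref_params <- fhn_params(I = 0.265, alpha = 0.7, beta = 0.75, epsilon = 0.08)
ref_eq <- equilibrium_analysis(ref_params)
ref_nf_unit <- build_normal_form(ref_eq, sigma0 = 1)

## Random parameter sets guaranteed to have a unique fixed point
## (beta < 1 makes the cubic discriminant positive).
random_excitable_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    fhn_params(I = runif(1, 0, 0.5), alpha = runif(1, 0.3, 1),
               beta = runif(1, 0.35, 0.95), epsilon = runif(1, 0.02, 0.3)))
}
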