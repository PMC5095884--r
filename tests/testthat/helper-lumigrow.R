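## Shared fixtures: the published cohort conditions used as ground truth in
## recovery tests, and a reduced SAEM schedule for cheap unit tests (the
## acceptance tests use the default schedule).

tab1 <- list(a = 0.399, K = 4.35e9, lam = 2.25,
             cv_a = 31.1, cv_K = 55.3, cv_lam = 10, rse_a = 7.02)

typical_params <- function(lam = tab1$lam)
  growth_params(a = tab1$a, K = tab1$K, P0 = 1.5e5 * 88.4, lam = lam)

fast_control <- function(...)
  saem_control(K1 = 120, K2 = 80, fim_samples = 40, ...)

## count of sign changes of a sequence, ignoring near-zero entries
n_sign_changes <- function(x, eps = 0) {
  s <- sign(x[abs(x) > eps])
  sum(diff(s) != 0)
}
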