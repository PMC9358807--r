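# Small deterministic datasets built in code for the unit tests.

# index-trial draw from the simulation engine's own generator
make_index <- function(n = 140, mean = 0.5, seed = 101) {
  set.seed(seed)
  sim_trial(n, mean, dgm_coefficients())
}

make_ald <- function(seed = 202, n = 300, mean = 0.6) {
  set.seed(seed)
  aggregate_ald(sim_trial(n, mean, dgm_coefficients()))
}

# independent 1-D oracle: the moment condition sum_i z*_i exp(z*_i a) = 0
# solved by bisection, no reuse of the package's optimizer
bisect_alpha <- function(zstar, lower = -50, upper = 50, tol = 1e-10) {
  g <- function(a) sum(zstar * exp(zstar * a))
  stats::uniroot(g, c(lower, upper), tol = tol)$root
}
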