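# Random but well-posed parameter sets used by the property-style tests.
# All generators assume the caller has fixed the RNG seed.

rand_single <- function(x0_frac_range = c(0.001, 0.4)) {
  N <- 10^runif(1, 2, 6)
  single_params(r = runif(1, 0.2, 1.5), N = N,
                x0 = runif(1, x0_frac_range[1], x0_frac_range[2]) * N)
}

rand_single_decline <- function() {
  N <- 10^runif(1, 2, 6)
  single_params(r = runif(1, 0.2, 1.5), N = N,
                x0 = runif(1, 1.2, 3) * N)
}

# coupled set with positive effective capacity and x0 below it
rand_coupled <- function() {
  N <- 10^runif(1, 2, 6)
  v <- runif(1, 10, 2000)
  # alpha*v/N uniform in (-0.8, 0.8): stays clear of the extinction bound
  alpha <- runif(1, -0.8, 0.8) * N / v
  Neff <- N + alpha * v
  p <- coupled_params(r = runif(1, 0.2, 1.5), N = N, alpha = alpha,
                      x0 = runif(1, 0.001, 0.3) * Neff)
  list(p = p, v = v)
}

# a feasible, stable coexistence set in a random regime
rand_coexist_stable <- function() {
  N1 <- 10^runif(1, 2, 5)
  N2 <- 10^runif(1, 2, 5)
  repeat {
    a1 <- runif(1, -0.9, 0.9) * N1 / N2
    a2 <- runif(1, -0.9, 0.9) * N2 / N1
    if (a1 * a2 < 0.9) break
  }
  coexist_params(r1 = runif(1, 0.3, 1.2), r2 = runif(1, 0.3, 1.2),
                 N1 = N1, N2 = N2, alpha1 = a1, alpha2 = a2,
                 x01 = runif(1, 0.01, 0.5) * N1,
                 x02 = runif(1, 0.01, 0.5) * N2)
}

# reference fishery parameter set used across the suite
fish_params <- function(x0 = 6000) single_params(r = 0.8, N = 780500, x0 = x0)

# maximum relative deviation between two positive trajectories
max_rel_err <- function(a, b) max(abs(a - b) / pmax(abs(b), .Machine$double.eps))
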