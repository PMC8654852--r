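# Shared fixtures: named strategies and a brute-force assessment oracle kept
# deliberately independent of the package's closed-form paths.

st_standing <- strategy(1, 0, 1, 1, 1, 1, 0, 1, 0, 1)
st_image    <- strategy(1, 0, 1, 1, 1, 1, 0, 0, 0, 0)
st_allc     <- as_strategy(rep(1L, 10))
st_alld     <- as_strategy(rep(0L, 10))
st_c5       <- as_strategy("1011110111")  # d11=0, d01=1 (C5-11 family)
st_c12      <- as_strategy("1011011101")  # d11=1, d01=0 (C12-15 family)

# brute-force p(new opinion = good): enumerate the four (i, k) opinion pairs
oracle_assess <- function(C, D, p_coop, h_d, h_r, mu_a = 0) {
  tot <- 0
  for (i in c(1, 0)) for (k in c(1, 0)) {
    w <- (if (i == 1) h_d else 1 - h_d) * (if (k == 1) h_r else 1 - h_r)
    idx <- (1 - i) * 2 + (1 - k) + 1
    for (coop in c(1, 0)) {
      p_act <- if (coop == 1) p_coop else 1 - p_coop
      rule <- if (coop == 1) C[idx] else D[idx]
      good <- rule * (1 - mu_a) + (1 - rule) * mu_a
      tot <- tot + w * p_act * good
    }
  }
  tot
}

# forward-integration oracle for the monomorphic dynamics (plain Euler)
oracle_mono_endpoint <- function(s, params, t_end = 400, dt = 0.1) {
  h <- params$h0
  for (i in seq_len(t_end / dt)) {
    h <- h + dt * monomorphic_derivative(s, h, params)
    h <- min(max(h, 0), 1)
  }
  h
}

# forward-integration oracle for the (h_mr, h_rm) system with h_rr held at
# its equilibrium, matching the solver's sequential formulation
oracle_dimorphic_endpoint <- function(resident, mutant, params,
                                      t_end = 400, dt = 0.05) {
  r_star <- unname(monomorphic_equilibrium(resident, params)$h_star[1])
  x <- params$h0; y <- params$h0
  for (i in seq_len(t_end / dt)) {
    d <- dimorphic_derivatives(resident, mutant, c(r_star, x, y), params)
    x <- min(max(x + dt * d[["dh_mr"]], 0), 1)
    y <- min(max(y + dt * d[["dh_rm"]], 0), 1)
  }
  c(h_rr = r_star, h_mr = x, h_rm = y)
}

rand_strategy <- function() as_strategy(sample(0:1, 10, replace = TRUE))
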