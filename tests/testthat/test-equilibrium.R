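p0 <- model_params(h0 = 0.5)

test_that("monomorphic equilibria match known cases", {
  eq <- monomorphic_equilibrium(st_standing, p0)
  expect_equal(unname(eq$h_star[1]), 1)
  expect_true(eq$converged)

  # derivative identically zero: stays at h0, marginal
  eq <- monomorphic_equilibrium(st_image, model_params(h0 = 0.9))
  expect_equal(unname(eq$h_star[1]), 0.9)
  expect_equal(eq$stable, "marginal")

  # all-assess-good with assessment error: p(o) = 1 - mu_a
  eq <- monomorphic_equilibrium(as_strategy("1011111111"),
                                model_params(mu_a = 0.01, h0 = 0.5))
  expect_equal(unname(eq$h_star[1]), 0.99, tolerance = 1e-9)
  expect_equal(eq$stable, "stable")
})

test_that("flow endpoint is a stable-or-marginal root and matches integration", {
  withr::with_seed(19, {
    for (i in 1:25) {
      s <- rand_strategy()
      pp <- model_params(mu_e = runif(1, 0, 0.2), mu_a = runif(1, 0, 0.2),
                         h0 = runif(1))
      eq <- monomorphic_equilibrium(s, pp)
      h <- unname(eq$h_star[1])
      expect_lte(abs(monomorphic_derivative(s, h, pp)), 1e-9)
      # endpoint is never a repeller
      expect_true(eq$stable %in% c("stable", "marginal"))
      # agreement with the independent explicit integrator
      expect_equal(h, oracle_mono_endpoint(s, pp), tolerance = 2e-2)
      # and with the package's own integrator at tight tolerance
      eq2 <- monomorphic_equilibrium(s, pp, method = "integrate")
      expect_equal(unname(eq2$h_star[1]), h, tolerance = 1e-4)
    }
  })
})

test_that("mirror symmetry of equilibria", {
  withr::with_seed(23, {
    for (i in 1:20) {
      s <- rand_strategy()
      h0 <- runif(1)
      mu <- runif(1, 0, 0.2)
      e1 <- monomorphic_equilibrium(s, model_params(mu_e = mu, mu_a = mu,
                                                    h0 = h0))
      e2 <- monomorphic_equilibrium(mirror_strategy(s),
                                    model_params(mu_e = mu, mu_a = mu,
                                                 h0 = 1 - h0))
      expect_equal(unname(e2$h_star[1]), 1 - unname(e1$h_star[1]),
                   tolerance = 1e-8)
    }
  })
})

test_that("basin selection depends on the initial h-score", {
  # 1011101000 is bistable: stable points at 0 and 1, repeller at 1/2
  s <- as_strategy("1011101000")
  expect_equal(unname(monomorphic_equilibrium(
    s, model_params(h0 = 0.05))$h_star[1]), 0)
  expect_equal(unname(monomorphic_equilibrium(
    s, model_params(h0 = 0.95))$h_star[1]), 1)
  # perturbing h0 inside a basin keeps the endpoint
  for (h0 in c(0.3, 0.7)) {
    e  <- monomorphic_equilibrium(s, model_params(h0 = h0))
    ep <- monomorphic_equilibrium(s, model_params(h0 = h0 + 1e-6))
    expect_equal(unname(e$h_star[1]), unname(ep$h_star[1]), tolerance = 1e-9)
  }
  # at the basin boundary the two sides separate (and the boundary itself
  # is an equilibrium)
  at <- monomorphic_equilibrium(s, model_params(h0 = 0.5))
  expect_equal(unname(at$h_star[1]), 0.5)
  below <- monomorphic_equilibrium(s, model_params(h0 = 0.5 - 1e-6))
  above <- monomorphic_equilibrium(s, model_params(h0 = 0.5 + 1e-6))
  expect_equal(unname(below$h_star[1]), 0)
  expect_equal(unname(above$h_star[1]), 1)
})

test_that("dimorphic equilibria match known cases", {
  # standing vs AllD: residents reach 1, the mutant's score decays to 0
  eq <- dimorphic_equilibrium(st_standing, st_alld,
                              model_params(b = 3, c = 1, h0 = 0.5))
  expect_equal(unname(eq$h_star), c(1, 0, 0), tolerance = 1e-9)
  expect_true(eq$converged)

  # C5-type resident (d11 = 0, d01 = 1): mutant defectors held at 1/2
  eq <- dimorphic_equilibrium(st_c5, st_alld, p0)
  expect_equal(unname(eq$h_star[["h_mr"]]), 0.5, tolerance = 1e-9)

  # C12-type resident (d11 = 1, d01 = 0): mutant score frozen at h(t0)
  eq <- dimorphic_equilibrium(st_c12, st_alld, model_params(h0 = 0.9))
  expect_equal(unname(eq$h_star[["h_mr"]]), 0.9, tolerance = 1e-9)
})

test_that("dimorphic solver agrees with an independent explicit integrator", {
  withr::with_seed(29, {
    for (i in 1:8) {
      res <- rand_strategy(); mut <- rand_strategy()
      pp <- model_params(mu_e = runif(1, 0, 0.1), mu_a = runif(1, 0, 0.1),
                         h0 = runif(1))
      eq <- dimorphic_equilibrium(res, mut, pp)
      ora <- oracle_dimorphic_endpoint(res, mut, pp)
      expect_equal(unname(eq$h_star[["h_mr"]]), unname(ora[["h_mr"]]),
                   tolerance = 2e-2)
      expect_equal(unname(eq$h_star[["h_rm"]]), unname(ora[["h_rm"]]),
                   tolerance = 2e-2)
    }
  })
})

test_that("identical mutant reproduces the monomorphic equilibrium", {
  for (s in list(st_standing, st_image, st_c5)) {
    mono <- monomorphic_equilibrium(s, p0)
    di <- dimorphic_equilibrium(s, s, p0)
    expect_equal(unname(di$h_star[["h_rr"]]), unname(mono$h_star[1]),
                 tolerance = 1e-9)
    expect_equal(unname(di$h_star[["h_rm"]]), unname(mono$h_star[1]),
                 tolerance = 1e-6)
  }
})
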