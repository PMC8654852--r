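p0 <- model_params(h0 = 0.5)

test_that("act_prob follows the action rule with execution error", {
  expect_equal(act_prob(1, 0, 1, 0), 1)
  expect_equal(act_prob(1, 0, 0.3, 0), 0.3)
  expect_equal(act_prob(0, 0, 0.77, 0.1), 0.1)     # raw = 0 -> mu_e
  expect_equal(act_prob(1, 1, 0.2, 0.05), 0.95)
  # always within [mu_e, 1 - mu_e]
  for (h in seq(0, 1, 0.25))
    for (a in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
      expect_true(act_prob(a[1], a[2], h, 0.2) >= 0.2 &&
                    act_prob(a[1], a[2], h, 0.2) <= 0.8)
  expect_error(act_prob(1, 0, 1.2, 0), "\\[0, 1\\]")
})

test_that("assess_prob_good agrees with brute-force enumeration", {
  expect_equal(assess_prob_good(rep(1, 4), rep(1, 4), 0.3, 0.6, 0.2, 0), 1)
  # image scoring collapses to p_coop
  expect_equal(assess_prob_good(rep(1, 4), rep(0, 4), 0.37, 0.8, 0.1, 0),
               0.37)
  # standing: given defection, good iff the observer deems the recipient bad
  h <- 0.3
  expect_equal(assess_prob_good(c(1, 1, 1, 1), c(0, 1, 0, 1),
                                h, h, h, 0), h + (1 - h)^2)
  withr::with_seed(7, {
    for (i in 1:30) {
      s <- rand_strategy()
      C <- as.integer(s[3:6]); D <- as.integer(s[7:10])
      pc <- runif(1); hd <- runif(1); hr <- runif(1); mu <- runif(1, 0, 0.4)
      expect_equal(assess_prob_good(C, D, pc, hd, hr, mu),
                   oracle_assess(C, D, pc, hd, hr, mu), tolerance = 1e-12)
    }
  })
  expect_error(assess_prob_good(rep(1, 4), rep(0, 4), 1.5, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("monomorphic derivative matches closed forms", {
  # image scoring: p(o) = p_coop = h, derivative vanishes identically
  for (h in seq(0, 1, 0.1))
    expect_equal(monomorphic_derivative(st_image, h, p0), 0, tolerance = 1e-14)
  # standing: (1 - h)^2
  for (h in c(0, 0.25, 0.5, 0.9, 1))
    expect_equal(monomorphic_derivative(st_standing, h, p0), (1 - h)^2,
                 tolerance = 1e-12)
  # all-assess-good at h = 1 is a fixed point
  expect_equal(monomorphic_derivative(as_strategy("1011111111"), 1, p0), 0)
  # mu_a = 0.5 forces p(o) = 1/2
  pa <- model_params(mu_a = 0.49999999, h0 = 0.5)
  pa$mu_a <- 0.5  # boundary case, bypassing the constructor's open interval
  for (i in 1:10) {
    s <- rand_strategy()
    expect_equal(monomorphic_derivative(s, 0.3, pa), 0.5 - 0.3,
                 tolerance = 1e-12)
  }
})

test_that("derivative is the stated polynomial of degree at most three", {
  withr::with_seed(11, {
    for (i in 1:40) {
      s <- rand_strategy()
      pp <- model_params(mu_e = runif(1, 0, 0.3), mu_a = runif(1, 0, 0.3))
      k <- derivative_poly(s, pp)
      expect_length(k, 4)
      # symbolic expansion agrees with direct evaluation everywhere
      for (h in c(0, 0.21, 0.5, 0.84, 1))
        expect_equal(sum(k * h^(0:3)), monomorphic_derivative(s, h, pp),
                     tolerance = 1e-12)
    }
  })
})

test_that("mirror symmetry: f_mirror(1 - h) = -f(h)", {
  withr::with_seed(3, {
    for (i in 1:40) {
      s <- rand_strategy()
      pp <- model_params(mu_e = runif(1, 0, 0.3), mu_a = runif(1, 0, 0.3))
      h <- runif(1)
      expect_equal(monomorphic_derivative(mirror_strategy(s), 1 - h, pp),
                   -monomorphic_derivative(s, h, pp), tolerance = 1e-12)
    }
  })
})

test_that("dimorphic derivatives: symmetry and closed-form anchors", {
  # mutant identical to resident at a symmetric state reduces to monomorphic
  st <- c(0.4, 0.4, 0.4)
  d <- dimorphic_derivatives(st_standing, st_standing, st, p0)
  expect_equal(unname(d[2]), unname(d[1]), tolerance = 1e-12)
  expect_equal(unname(d[3]), unname(d[1]), tolerance = 1e-12)
  # standing resident at h_rr = 1 vs AllD: dh_mr = -h_mr
  for (hmr in c(0.1, 0.6, 1)) {
    d <- dimorphic_derivatives(st_standing, st_alld, c(1, hmr, 0.5), p0)
    expect_equal(unname(d[["dh_mr"]]), -hmr, tolerance = 1e-12)
  }
  # d = (1,*,0,*) resident at h_rr = 1 vs AllD: dh_mr = 0 for all h_mr
  for (hmr in c(0, 0.3, 0.9))
    expect_equal(unname(dimorphic_derivatives(
      st_c12, st_alld, c(1, hmr, 0.2), p0)[["dh_mr"]]), 0, tolerance = 1e-12)
  expect_error(dimorphic_derivatives(st_c12, st_alld, c(1.2, 0, 0), p0),
               "\\[0, 1\\]")
})

test_that("parameter validation rejects out-of-range inputs", {
  expect_error(model_params(b = 1, c = 1), "exceed")
  expect_error(model_params(mu_e = 0.7), "0.5")
  expect_error(model_params(h0 = 1.4), "\\[0, 1\\]")
})
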