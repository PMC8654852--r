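p05 <- model_params(b = 3, c = 1, h0 = 0.5)

test_that("invasion fitness anchors", {
  # identical mutant: exactly zero, resists
  f <- invasion_fitness(st_standing, st_standing, p05)
  expect_equal(f$delta_w, 0, tolerance = 1e-9)
  expect_false(f$invades)

  # standing vs AllD at b = 3: 0*3 - 0*1 - (3-1)*1 = -2
  f <- invasion_fitness(st_standing, st_alld, p05)
  expect_equal(f$delta_w, -2, tolerance = 1e-8)
  expect_false(f$invades)

  # C5-type vs AllD at b = 2: 0.5*2 - 0 - 1 = 0 -> tie resists
  f <- invasion_fitness(st_c5, st_alld, model_params(b = 2, c = 1, h0 = 0.5))
  expect_equal(f$delta_w, 0, tolerance = 1e-8)
  expect_false(f$invades)
})

test_that("equality resists invasion at the printed tolerance", {
  # C5 vs AllD has dw = 1 - b/2: positive below b = 2, but differences
  # inside the 1e-4 tolerance are ties
  f <- invasion_fitness(st_c5, st_alld,
                        model_params(b = 1.9999, c = 1, h0 = 0.5))
  expect_equal(f$delta_w, 5e-5, tolerance = 1e-8)
  expect_false(f$invades)   # 5e-5 above zero: still a tie
  f <- invasion_fitness(st_c5, st_alld,
                        model_params(b = 1.99, c = 1, h0 = 0.5))
  expect_equal(f$delta_w, 5e-3, tolerance = 1e-8)
  expect_true(f$invades)
})

test_that("AllD is an ESS with and without errors", {
  expect_true(is_ess(st_alld, model_params(b = 5, c = 1, h0 = 0.5))$is_ess)
  expect_true(is_ess(st_alld, model_params(b = 20, c = 1, mu_e = 0.01,
                                           mu_a = 0.01, h0 = 0.5))$is_ess)
})

test_that("image scoring is never an ESS", {
  for (h0 in c(0.1, 0.5, 0.9)) {
    for (b in c(1.5, 5)) {
      v <- is_ess(st_image, model_params(b = b, c = 1, h0 = h0))
      expect_false(isTRUE(v$is_ess))
      expect_gt(length(v$invaders), 0)
    }
  }
})

test_that("minimum benefit-to-cost thresholds per cooperator family", {
  expect_equal(min_bc_threshold(st_standing, h0 = 0.5)$threshold, 1,
               tolerance = 1e-6)
  expect_equal(min_bc_threshold(st_c5, h0 = 0.5)$threshold, 2,
               tolerance = 1e-6)
  expect_equal(min_bc_threshold(st_c5, h0 = 0.9)$threshold, 2,
               tolerance = 1e-6)
  # C12-15: threshold 1/(1 - h0)
  for (h0 in c(0.5, 0.9))
    expect_equal(min_bc_threshold(st_c12, h0 = h0)$threshold, 1 / (1 - h0),
                 tolerance = 1e-6)
})

test_that("classification by resident-resident cooperation", {
  expect_equal(classify_strategy(st_standing, model_params(h0 = 0.5)),
               "cooperator")
  expect_equal(classify_strategy(st_alld, model_params(h0 = 0.5)), "defector")
  expect_equal(classify_strategy(st_image, model_params(h0 = 0.5)),
               "intermediate")
})

test_that("polymorphism requires mutual invasion", {
  expect_false(polymorphism_check(st_standing, st_standing, p05))
  # standing earns nothing against AllD residents: no mutual invasion
  expect_false(polymorphism_check(st_alld, st_standing, p05))
})

test_that("scan on a resident subset reproduces thresholds and classes", {
  subset <- list(st_standing, st_c5, st_c12, st_alld, st_image)
  scan <- ess_scan(residents = subset)
  rec <- scan$records
  expect_equal(nrow(rec), 5)
  expect_true(all(rec$converged))
  g <- scan$grid
  r <- function(code) rec[rec$code == code, ]
  expect_true(r(757)$ess_all_h0)                # standing: ESS everywhere
  expect_equal(r(757)$class, "cooperator")
  expect_equal(r(encode_strategy(st_c5))$threshold_max, 2, tolerance = 1e-6)
  # C12-15 common threshold is set by h0 = 0.9: 1/(1 - 0.9) = 10
  expect_equal(r(encode_strategy(st_c12))$threshold_max, 10, tolerance = 1e-6)
  expect_true(r(0)$ess_all_h0)                  # AllD
  expect_equal(r(0)$class, "defector")
  # image scoring ties everything at the b = c end of the axis but is
  # intermediate (p_rr = h0), hence in neither headline class, and it is
  # invaded at every ratio strictly above cost
  expect_equal(r(encode_strategy(st_image))$class, "intermediate")
  img <- g[g$code == encode_strategy(st_image) & g$bc > 1, ]
  expect_false(any(img$is_ess))
  # grid rows sorted by (code, h0, bc) and consistent with verdicts
  expect_false(is.unsorted(order(g$code, g$h0, g$bc)))
  expect_identical(g$is_ess, g$delta_w_max <= 1e-4)
})

test_that("cooperator thresholds are monotone in b", {
  scan <- ess_scan(residents = list(st_standing, st_c5, st_c12))
  g <- scan$grid
  for (code in unique(g$code)) {
    for (h0 in c(0.1, 0.5, 0.9)) {
      v <- g$is_ess[g$code == code & g$h0 == h0]
      # once ESS, stays ESS at every larger ratio
      if (any(v)) expect_true(all(v[seq(which.max(v), length(v))]))
    }
  }
})
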