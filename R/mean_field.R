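#' Model parameters
#'
#' @param b benefit of receiving cooperation (must exceed `c`: the game is a
#'   social dilemma).
#' @param c cost of cooperating (the analysis normalises `c = 1`).
#' @param mu_e execution error rate in `[0, 0.5)`: the donor does the
#'   opposite of what its action rule prescribes.
#' @param mu_a assessment error rate in `[0, 0.5)`: the observer records the
#'   opposite of the opinion its assessment rule prescribes.
#' @param h0 shared initial h-score in `[0, 1]` (every individual, resident
#'   or mutant, starts with the same average reputation).
#' @return a validated list of class `ir_params`.
#' @export
model_params <- function(b = 2, c = 1, mu_e = 0, mu_a = 0, h0 = 0.5) {
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b), b > 0,
            is.numeric(c), length(c) == 1L, is.finite(c), c > 0)
  if (b <= c)
    stop("benefit b must exceed cost c (social dilemma), got b = ", b,
         ", c = ", c)
  for (nm in c("mu_e", "mu_a")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v >= 0.5)
      stop(nm, " must lie in [0, 0.5), got ", v)
  }
  if (!is.numeric(h0) || length(h0) != 1L || is.na(h0) || h0 < 0 || h0 > 1)
    stop("h0 must lie in [0, 1], got ", h0)
  structure(list(b = b, c = c, mu_e = mu_e, mu_a = mu_a, h0 = h0),
            class = "ir_params")
}

#' @export
print.ir_params <- function(x, ...) {
  cat(sprintf("<params b=%g c=%g mu_e=%g mu_a=%g h0=%g>\n",
              x$b, x$c, x$mu_e, x$mu_a, x$h0))
  invisible(x)
}

check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(what, " must lie in [0, 1], got ", paste(x, collapse = ", "))
  invisible(x)
}

#' Probability of cooperation given an action rule
#'
#' The donor cooperates with probability `h a1 + (1 - h) a0` where `h` is the
#' chance it deems the recipient good; an execution error then flips the
#' realised action with probability `mu_e`, so the result lies in
#' `[mu_e, 1 - mu_e]`.
#'
#' @param a1,a0 action bits.
#' @param h probability the donor holds opinion "good" of the recipient
#'   (vectorised).
#' @param mu_e execution error rate.
#' @return probability of observed cooperation.
#' @export
act_prob <- function(a1, a0, h, mu_e = 0) {
  check_prob(h, "h")
  raw <- h * a1 + (1 - h) * a0
  raw * (1 - mu_e) + (1 - raw) * mu_e
}

# q(): assessment error applied to a prescribed opinion bit (or probability)
assess_err <- function(x, mu_a) x * (1 - mu_a) + (1 - x) * mu_a

#' Probability an observer assigns a good opinion to the donor
#'
#' Mean-field form of one assessment event.  The observer's current opinions
#' of donor and recipient are independent Bernoulli draws with success
#' probabilities `h_donor` and `h_recip` (well-mixed infinite population);
#' the assessment rule then prescribes `c_ik` (after a cooperation, with
#' probability `p_coop`) or `d_ik` (after a defection), and an assessment
#' error flips the recorded opinion with probability `mu_a`.
#'
#' @param C,D assessment bit vectors `(x11, x10, x01, x00)`.
#' @param p_coop probability the donor (visibly) cooperated.
#' @param h_donor,h_recip probabilities the observer deems the donor /
#'   recipient good.
#' @param mu_a assessment error rate.
#' @return probability the observer's new opinion of the donor is good.
#' @export
assess_prob_good <- function(C, D, p_coop, h_donor, h_recip, mu_a = 0) {
  stopifnot(length(C) == 4L, length(D) == 4L)
  check_prob(c(p_coop, h_donor, h_recip), "probabilities")
  w_d <- c(h_donor, h_donor, 1 - h_donor, 1 - h_donor)  # i = 1,1,0,0
  w_r <- c(h_recip, 1 - h_recip, h_recip, 1 - h_recip)  # k = 1,0,1,0
  good_c <- sum(w_d * w_r * assess_err(C, mu_a))
  good_d <- sum(w_d * w_r * assess_err(D, mu_a))
  p_coop * good_c + (1 - p_coop) * good_d
}

strat_C <- function(s) as.integer(s[3:6])
strat_D <- function(s) as.integer(s[7:10])

#' h-score time derivative in a monomorphic population
#'
#' `dh/dt = p(o) - h`, where `p(o)` is the probability that a random observer
#' assigns a good opinion to a random donor, both drawn from the resident
#' population with average reputation `h`.  A polynomial in `h` of degree at
#' most three.
#'
#' @inheritParams encode_strategy
#' @param h current h-score (vectorised).
#' @param params an `ir_params`.
#' @return the derivative, in `[-1, 1]`.
#' @export
monomorphic_derivative <- function(s, h, params = model_params()) {
  s <- as_strategy(s)
  check_prob(h, "h")
  vapply(h, function(hh) {
    p_coop <- act_prob(s[["a1"]], s[["a0"]], hh, params$mu_e)
    assess_prob_good(strat_C(s), strat_D(s), p_coop, hh, hh, params$mu_a) - hh
  }, 0)
}

#' Coefficients of the monomorphic derivative polynomial
#'
#' Expands `dh/dt` for a strategy as `k0 + k1 h + k2 h^2 + k3 h^3` (exact,
#' not fitted).  Useful for root cross-checks and audit export.
#'
#' @inheritParams monomorphic_derivative
#' @return numeric coefficient vector, constant term first.
#' @export
derivative_poly <- function(s, params = model_params()) {
  s <- as_strategy(s)
  qC <- assess_err(strat_C(s), params$mu_a)
  qD <- assess_err(strat_D(s), params$mu_a)
  # S(h) = q00 + (q10 + q01 - 2 q00) h + (q11 - q10 - q01 + q00) h^2
  quad <- function(q) c(q[4L], q[2L] + q[3L] - 2 * q[4L],
                        q[1L] - q[2L] - q[3L] + q[4L])
  sc <- quad(qC); sd <- quad(qD)
  # p_coop(h) = e0 + e1 h
  e0 <- s[["a0"]] * (1 - 2 * params$mu_e) + params$mu_e
  e1 <- (s[["a1"]] - s[["a0"]]) * (1 - 2 * params$mu_e)
  diff <- sc - sd
  # P(h) = S_D + p_coop (S_C - S_D); deriv = P - h
  k <- c(sd, 0) + e0 * c(diff, 0) + e1 * c(0, diff)
  k[2L] <- k[2L] - 1
  unname(k)
}

#' h-score state for a resident-plus-rare-mutant population
#'
#' @param h_rr residents' average opinion of a resident.
#' @param h_mr residents' average opinion of the mutant.
#' @param h_rm mutant's average opinion of a resident.
#' @return a named numeric vector of class `ir_hstate`.
#' @export
h_state <- function(h_rr, h_mr, h_rm) {
  x <- c(h_rr = h_rr, h_mr = h_mr, h_rm = h_rm)
  check_prob(x, "h-state coordinates")
  class(x) <- "ir_hstate"
  x
}

#' h-score derivatives with a rare mutant present
#'
#' Three coupled equations.  The resident coordinate `h_rr` evolves as in the
#' monomorphic case (the rare mutant's effect on residents is negligible).
#' `h_mr` (residents' opinion of the mutant) changes when a resident observes
#' the mutant donating to a resident: the mutant acts using its own opinion
#' of residents (`h_rm`), and the observer judges with its opinions of donor
#' (`h_mr`) and recipient (`h_rr`).  `h_rm` (the mutant's opinion of
#' residents) changes when the mutant observes resident-resident
#' interactions, judging with its own assessment rules and opinions (`h_rm`
#' for both parties), while the resident donor acts on `h_rr`.
#'
#' @param resident,mutant `ir_strategy` objects.
#' @param state an [h_state()] (or plain numeric `(h_rr, h_mr, h_rm)`).
#' @param params an `ir_params`.
#' @return named numeric vector `(dh_rr, dh_mr, dh_rm)`.
#' @export
dimorphic_derivatives <- function(resident, mutant, state,
                                  params = model_params()) {
  resident <- as_strategy(resident); mutant <- as_strategy(mutant)
  state <- as.numeric(state)
  if (length(state) != 3L) stop("state must hold (h_rr, h_mr, h_rm)")
  check_prob(state, "state")
  h_rr <- state[1L]; h_mr <- state[2L]; h_rm <- state[3L]
  dh_rr <- monomorphic_derivative(resident, h_rr, params)
  p_mut <- act_prob(mutant[["a1"]], mutant[["a0"]], h_rm, params$mu_e)
  dh_mr <- assess_prob_good(strat_C(resident), strat_D(resident),
                            p_mut, h_mr, h_rr, params$mu_a) - h_mr
  p_res <- act_prob(resident[["a1"]], resident[["a0"]], h_rr, params$mu_e)
  dh_rm <- assess_prob_good(strat_C(mutant), strat_D(mutant),
                            p_res, h_rm, h_rm, params$mu_a) - h_rm
  c(dh_rr = dh_rr, dh_mr = unname(dh_mr), dh_rm = unname(dh_rm))
}
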