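#' Agent-based simulation configuration
#'
#' Defaults follow the validation protocol: 100 individuals, one observer
#' per interaction, 4e5 interactions with the last 1e5 averaged, 30
#' replicates.
#'
#' @param n population size (>= 3).
#' @param total_interactions interactions per replicate.
#' @param averaging_window final interactions averaged into the summary.
#' @param replicates independent replicates.
#' @param observers_per_interaction observers drawn per interaction
#'   (currently 1).
#' @param h0 initial probability that an opinion is good.
#' @param mu_e,mu_a execution / assessment error rates.
#' @param seed RNG seed; each replicate runs on an independent substream
#'   derived from `(seed, replicate)`.
#' @param observer_can_be_recipient if `TRUE` the recipient may observe its
#'   own interaction (the default excludes both parties).
#' @return a validated list of class `ir_sim_config`.
#' @export
sim_config <- function(n = 100, total_interactions = 4e5,
                       averaging_window = 1e5, replicates = 30,
                       observers_per_interaction = 1, h0 = 0.5,
                       mu_e = 1e-4, mu_a = 1e-4, seed = 1,
                       observer_can_be_recipient = FALSE) {
  stopifnot(n >= 3, total_interactions >= 1,
            averaging_window >= 1, replicates >= 1)
  if (averaging_window > total_interactions)
    stop("averaging_window (", averaging_window,
         ") exceeds total_interactions (", total_interactions, ")")
  if (observers_per_interaction != 1)
    stop("only one observer per interaction is supported")
  if (observers_per_interaction > n - 2)
    stop("not enough bystanders to observe")
  for (nm in c("mu_e", "mu_a")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v >= 0.5)
      stop(nm, " must lie in [0, 0.5), got ", v)
  }
  if (h0 < 0 || h0 > 1) stop("h0 must lie in [0, 1]")
  structure(list(n = as.integer(n),
                 total_interactions = as.integer(total_interactions),
                 averaging_window = as.integer(averaging_window),
                 replicates = as.integer(replicates),
                 observers_per_interaction = 1L,
                 h0 = h0, mu_e = mu_e, mu_a = mu_a, seed = as.integer(seed),
                 observer_can_be_recipient = observer_can_be_recipient),
            class = "ir_sim_config")
}

#' Initialise a private-opinion matrix
#'
#' Each individual holds an opinion of every other individual (never of
#' itself): entry `[i, j]` is i's opinion of j, drawn i.i.d. Bernoulli(h0);
#' the diagonal is `NA` and is never read or written.
#'
#' @param config an `ir_sim_config`.
#' @return an `n x n` integer matrix with `NA` diagonal.
#' @export
init_population <- function(config = sim_config()) {
  n <- config$n
  op <- matrix(as.integer(stats::runif(n * n) < config$h0), n, n)
  diag(op) <- NA_integer_
  op
}

#' One donation-game interaction (reference implementation)
#'
#' Draws donor and recipient uniformly without replacement; the donor acts on
#' its own opinion of the recipient (`a1`/`a0`), flipped with probability
#' `mu_e`; one observer drawn from the bystanders updates its opinion of the
#' donor according to its assessment rules and current opinions of donor and
#' recipient, flipped with probability `mu_a`.  Nothing else changes.  This
#' pure-R step is the testable reference for the compiled loop in
#' [run_abm()].
#'
#' @param op opinion matrix from [init_population()].
#' @inheritParams monomorphic_derivative
#' @param config an `ir_sim_config`.
#' @return list: updated `op`, realised `action` (1 = cooperation), and the
#'   drawn `donor`, `recipient`, `observer` indices.
#' @export
interaction_step <- function(op, s, config = sim_config()) {
  s <- as_strategy(s)
  n <- nrow(op)
  pair <- sample.int(n, 2L)
  donor <- pair[1L]; recip <- pair[2L]
  intended <- if (op[donor, recip] == 1L) s[["a1"]] else s[["a0"]]
  action <- if (stats::runif(1) < config$mu_e) 1L - intended else intended
  excl <- if (config$observer_can_be_recipient) donor else c(donor, recip)
  obs <- sample(setdiff(seq_len(n), excl), 1L)
  i <- op[obs, donor]; k <- op[obs, recip]
  rule <- if (action == 1L) strat_C(s) else strat_D(s)
  # rule order (11, 10, 01, 00)
  new_op <- rule[(1L - i) * 2L + (1L - k) + 1L]
  if (stats::runif(1) < config$mu_a) new_op <- 1L - new_op
  op[obs, donor] <- new_op
  list(op = op, action = action, donor = donor, recipient = recip,
       observer = obs)
}

#' Run the agent-based model
#'
#' Simulates the full interaction protocol for a monomorphic population and
#' summarises the final `averaging_window` interactions of each replicate.
#' The compiled engine is bit-for-bit reproducible for a given seed and
#' replicate index; `engine = "r"` runs the [interaction_step()] reference
#' (slow, for cross-validation at small sizes, driven by R's RNG).
#'
#' @inheritParams monomorphic_derivative
#' @param config an `ir_sim_config`.
#' @param engine `"cpp"` (default) or `"r"`.
#' @return a list of class `ir_sim_result`: `mean_h`, `mean_coop` (averages
#'   over window and replicates) and `per_replicate` (a data.frame).
#' @export
run_abm <- function(s, config = sim_config(), engine = c("cpp", "r")) {
  s <- as_strategy(s)
  engine <- match.arg(engine)
  if (engine == "cpp") {
    m <- run_abm_cpp(as.integer(s), config$n, config$total_interactions,
                     config$averaging_window, config$replicates, config$h0,
                     config$mu_e, config$mu_a, config$seed,
                     config$observer_can_be_recipient)
  } else {
    m <- matrix(0, config$replicates, 2,
                dimnames = list(NULL, c("mean_h", "mean_coop")))
    n <- config$n
    denom <- n * (n - 1)
    burn <- config$total_interactions - config$averaging_window
    for (rep in seq_len(config$replicates)) {
      set.seed(config$seed * 1000L + rep)
      op <- init_population(config)
      ones <- sum(op, na.rm = TRUE)
      h_acc <- 0; coop_acc <- 0L
      for (step in seq_len(config$total_interactions)) {
        st <- interaction_step(op, s, config)
        ones <- ones + sum(st$op, na.rm = TRUE) - sum(op, na.rm = TRUE)
        op <- st$op
        if (step > burn) {
          h_acc <- h_acc + ones / denom
          coop_acc <- coop_acc + st$action
        }
      }
      m[rep, ] <- c(h_acc / config$averaging_window,
                    coop_acc / config$averaging_window)
    }
  }
  per_rep <- data.frame(replicate = seq_len(config$replicates),
                        mean_h = m[, "mean_h"], mean_coop = m[, "mean_coop"])
  structure(list(mean_h = mean(m[, "mean_h"]),
                 mean_coop = mean(m[, "mean_coop"]),
                 per_replicate = per_rep, config = config),
            class = "ir_sim_result")
}

#' @export
print.ir_sim_result <- function(x, ...) {
  cat(sprintf("<abm result: mean_h %.4f  mean_coop %.4f  (%d reps)>\n",
              x$mean_h, x$mean_coop, nrow(x$per_replicate)))
  invisible(x)
}

#' Validate the mean-field model against the agent-based model
#'
#' Runs the simulator for each strategy and compares its long-run h-score
#' and realised cooperation frequency to the analytic equilibrium reached
#' from the same initial h-score.  The "absence of error" condition keeps a
#' tiny error rate in the simulation (default 1e-4) against an error-free
#' analytic prediction.
#'
#' @param strategies list of `ir_strategy` (default: the canonical 258).
#' @param config an `ir_sim_config` (its `mu_e`, `mu_a` apply to the
#'   simulation side).
#' @param analytic_params `ir_params` for the analytic side; its `h0` must
#'   match the simulation's.
#' @return a list of class `ir_abm_compare`: per-strategy data.frame and the
#'   mean absolute discrepancies `mean_dh`, `mean_dcoop`.
#' @export
compare_to_analytic <- function(strategies = canonical_set(),
                                config = sim_config(),
                                analytic_params = model_params(
                                  mu_e = 0, mu_a = 0, h0 = config$h0)) {
  if (!isTRUE(all.equal(analytic_params$h0, config$h0)))
    stop("analytic h0 (", analytic_params$h0,
         ") must match the simulation's (", config$h0, ")")
  rows <- lapply(strategies, function(s) {
    s <- as_strategy(s)
    eq <- monomorphic_equilibrium(s, analytic_params)
    h_pred <- unname(eq$h_star[1L])
    coop_pred <- act_prob(s[["a1"]], s[["a0"]], h_pred, analytic_params$mu_e)
    sim <- run_abm(s, config)
    data.frame(code = encode_strategy(s), h_pred = h_pred,
               h_sim = sim$mean_h, coop_pred = coop_pred,
               coop_sim = sim$mean_coop, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$abs_dh <- abs(tab$h_sim - tab$h_pred)
  tab$abs_dcoop <- abs(tab$coop_sim - tab$coop_pred)
  structure(list(table = tab, mean_dh = mean(tab$abs_dh),
                 mean_dcoop = mean(tab$abs_dcoop)),
            class = "ir_abm_compare")
}

#' @export
print.ir_abm_compare <- function(x, ...) {
  cat(sprintf(
    "<abm vs analytic: %d strategies  mean|dh| %.4f  mean|dcoop| %.4f>\n",
    nrow(x$table), x$mean_dh, x$mean_dcoop))
  invisible(x)
}
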