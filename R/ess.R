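FITNESS_TOL <- 1e-4  # fitness differences below this count as equal

# Equilibrium cooperation probabilities of one resident against a batch of
# mutants at a given initial h-score.  The resident equilibrium (and hence
# everything here) does not involve payoffs, so one call serves the whole
# benefit/cost grid.
invasion_table <- function(resident, mutants, params) {
  resident <- as_strategy(resident)
  mono <- monomorphic_equilibrium(resident, params)
  r_star <- unname(mono$h_star[1L])
  mut_mat <- do.call(rbind, lapply(mutants, as.integer))
  eq <- solve_dimorphic_batch(as.integer(resident), r_star, mut_mat,
                              params$h0, params$mu_e, params$mu_a)
  a_res <- c(resident[["a1"]], resident[["a0"]])
  p_rr <- act_prob(a_res[1L], a_res[2L], r_star, params$mu_e)
  p_mr <- act_prob(a_res[1L], a_res[2L], eq[, "h_mr"], params$mu_e)
  p_rm <- vapply(seq_along(mutants), function(j) {
    m <- mutants[[j]]
    act_prob(m[["a1"]], m[["a0"]], eq[j, "h_rm"], params$mu_e)
  }, 0)
  data.frame(
    mutant_code = vapply(mutants, encode_strategy, 0),
    h_rr = r_star, h_mr = eq[, "h_mr"], h_rm = eq[, "h_rm"],
    p_rr = p_rr, p_mr = p_mr, p_rm = p_rm,
    converged = eq[, "converged"] > 0 & mono$converged,
    stringsAsFactors = FALSE)
}

#' Invasion fitness of a rare mutant
#'
#' Computes the fitness difference `dw = p*(c_mr) b - p*(c_rm) c -
#' p*(c_rr) (b - c)` at the dimorphic equilibrium reached from the shared
#' initial h-score: the benefit the mutant receives from residents, minus the
#' cost of its own cooperation, minus the resident payoff.  A mutant invades
#' only if its fitness exceeds the resident's by more than the `1e-4`
#' floating-point tolerance; exact ties resist (no drift in an infinite
#' population).
#'
#' @param resident,mutant `ir_strategy` objects.
#' @param params an `ir_params` carrying `b`, `c`, errors and `h0`.
#' @param tol fitness tolerance.
#' @return a list of class `ir_invasion`: `delta_w`, `invades`, the three
#'   equilibrium cooperation probabilities `p_mr`, `p_rm`, `p_rr`, and
#'   `converged`.
#' @export
invasion_fitness <- function(resident, mutant, params = model_params(),
                             tol = FITNESS_TOL) {
  tab <- invasion_table(resident, list(as_strategy(mutant)), params)
  delta_w <- tab$p_mr * params$b - tab$p_rm * params$c -
    tab$p_rr * (params$b - params$c)
  structure(list(delta_w = delta_w, invades = delta_w > tol,
                 p_mr = tab$p_mr, p_rm = tab$p_rm, p_rr = tab$p_rr,
                 converged = tab$converged),
            class = "ir_invasion")
}

#' @export
print.ir_invasion <- function(x, ...) {
  cat(sprintf("<invasion dw = %+.6g  %s  (p_mr %.4g, p_rm %.4g, p_rr %.4g)>\n",
              x$delta_w, if (x$invades) "INVADES" else "resists",
              x$p_mr, x$p_rm, x$p_rr))
  invisible(x)
}

#' Is a resident strategy an ESS?
#'
#' Scans all other canonical strategies as rare mutants at the benefit and
#' cost in `params`.  Any failed equilibrium computation yields verdict
#' `NA` ("unknown"), never a silent `FALSE`.
#'
#' @inheritParams invasion_fitness
#' @param resident an `ir_strategy` (conventionally from [canonical_set()]).
#' @return a list: `is_ess` (logical, `NA` if unknown), `invaders` (codes of
#'   successful mutants), `max_delta_w`.
#' @export
is_ess <- function(resident, params = model_params(), tol = FITNESS_TOL) {
  resident <- as_strategy(resident)
  rcode <- encode_strategy(resident)
  mutants <- Filter(function(s) encode_strategy(s) != rcode, canonical_set())
  tab <- invasion_table(resident, mutants, params)
  dw <- tab$p_mr * params$b - tab$p_rm * params$c -
    tab$p_rr * (params$b - params$c)
  invaders <- tab$mutant_code[dw > tol]
  if (!all(tab$converged))
    return(list(is_ess = NA, invaders = invaders, max_delta_w = max(dw)))
  list(is_ess = length(invaders) == 0L, invaders = invaders,
       max_delta_w = max(dw))
}

# slope/intercept of dw as a function of b (cost normalised to 1):
# dw(b) = (p_mr - p_rr) b + (p_rr - p_rm)
dw_affine <- function(tab) {
  list(slope = tab$p_mr - tab$p_rr, intercept = tab$p_rr - tab$p_rm)
}

#' Minimum benefit-to-cost ratio for evolutionary stability
#'
#' With cost normalised to 1, each mutant's fitness advantage is affine in
#' `b`, so its critical ratio solves `dw = 0` exactly.  The threshold is the
#' largest such critical ratio among mutants that invade below it; it is
#' `NA` if some mutant still invades at arbitrarily large `b` within the
#' scan range.
#'
#' @param resident an `ir_strategy`.
#' @param h0 initial h-score.
#' @param params an `ir_params` (its `b`, `c` are ignored; `c` is 1).
#' @param bc_max upper end of the ratio range scanned.
#' @param tol fitness tolerance.
#' @return a list: `threshold` (numeric or `NA`), `binding_mutant` (code of
#'   the mutant that sets it, `NA` when the bound is the trivial `b > c`).
#' @export
min_bc_threshold <- function(resident, h0 = 0.5, params = model_params(),
                             bc_max = 20, tol = FITNESS_TOL) {
  params <- model_params(b = 2, c = 1, mu_e = params$mu_e,
                         mu_a = params$mu_a, h0 = h0)
  resident <- as_strategy(resident)
  rcode <- encode_strategy(resident)
  mutants <- Filter(function(s) encode_strategy(s) != rcode, canonical_set())
  tab <- invasion_table(resident, mutants, params)
  aff <- dw_affine(tab)
  eps <- 1e-12
  # mutants whose advantage grows with b can never be shut out
  open_ended <- (aff$slope > eps & aff$slope * bc_max + aff$intercept > tol) |
    (abs(aff$slope) <= eps & aff$intercept > tol)
  if (any(open_ended))
    return(list(threshold = NA_real_,
                binding_mutant = tab$mutant_code[which(open_ended)[1L]]))
  crit <- ifelse(aff$slope < -eps, -aff$intercept / aff$slope, -Inf)
  idx <- which.max(crit)
  thr <- max(1, crit[idx])
  list(threshold = thr,
       binding_mutant = if (crit[idx] > 1) tab$mutant_code[idx] else NA_real_)
}

#' Cooperator / defector classification
#'
#' Classifies a resident by its equilibrium cooperation rate with itself:
#' cooperator if `p_rr >= 1 - eps_class`, defector if `p_rr <= eps_class`,
#' otherwise intermediate (without errors the relevant rates are exactly 1
#' or 0).
#'
#' @inheritParams min_bc_threshold
#' @param eps_class classification tolerance.
#' @return `"cooperator"`, `"defector"` or `"intermediate"`.
#' @export
classify_strategy <- function(resident, params = model_params(),
                              eps_class = 1e-3) {
  resident <- as_strategy(resident)
  mono <- monomorphic_equilibrium(resident, params)
  p_rr <- act_prob(resident[["a1"]], resident[["a0"]],
                   unname(mono$h_star[1L]), params$mu_e)
  if (p_rr >= 1 - eps_class) "cooperator"
  else if (p_rr <= eps_class) "defector"
  else "intermediate"
}

#' Exhaustive evolutionary-invasion scan
#'
#' For every canonical resident, every initial h-score in `h0_set` and every
#' benefit-to-cost ratio on the grid, decides whether the resident resists
#' all 257 other canonical mutants.  Equilibria carry no payoffs, so each
#' (resident, mutant, h0) triple is solved once and reused across the whole
#' grid.  The headline classification keeps residents that are ESS at all
#' initial h-scores simultaneously for at least one common ratio, split into
#' cooperators (`p_rr = 1` at every h0) and defectors (`p_rr = 0`).
#'
#' @param bc_grid benefit-to-cost ratios scanned (cost 1).
#' @param h0_set initial h-scores.
#' @param mu_e,mu_a error rates.
#' @param tol fitness tolerance.
#' @param eps_class classification tolerance for [classify_strategy()].
#' @param residents optional subset of residents (default: full canonical
#'   set).
#' @param progress print a dot every 32 residents.
#' The default grid follows the figures' axis: ratios from 1 (where exact
#' fitness ties resist) to 20 in quarter-unit steps.  Alongside the per-grid
#' verdicts, the records report the exact tolerance-inclusive resist window
#' (each mutant's fitness advantage is affine in `b`, so window ends solve
#' `dw = tol` in closed form).
#'
#' @return a list of class `ir_ess_scan`:
#'   * `records`: one row per resident with class, headline ESS verdict,
#'     the common resist window `[min_bc_common, max_bc_common]` and the
#'     worst-case tolerance-free threshold `threshold_max`;
#'   * `grid`: one row per (resident, h0, bc) with the ESS verdict and the
#'     largest fitness advantage among mutants;
#'   * `summary`: headline counts.
#' @export
ess_scan <- function(bc_grid = seq(1, 20, by = 0.25),
                     h0_set = c(0.1, 0.5, 0.9),
                     mu_e = 0, mu_a = 0, tol = FITNESS_TOL,
                     eps_class = 1e-3, residents = canonical_set(),
                     progress = FALSE) {
  if (length(bc_grid) == 0L || any(bc_grid < 1))
    stop("bc_grid must contain ratios of at least 1")
  bc_grid <- sort(bc_grid)
  full <- canonical_set()
  codes_full <- vapply(full, encode_strategy, 0)
  n_r <- length(residents)
  n_b <- length(bc_grid)
  n_h <- length(h0_set)

  rec <- vector("list", n_r)
  grid_rows <- vector("list", n_r)
  for (i in seq_len(n_r)) {
    res <- as_strategy(residents[[i]])
    rcode <- encode_strategy(res)
    mutants <- full[codes_full != rcode]
    ess_by_h0 <- matrix(FALSE, n_h, n_b)
    thr_h0 <- numeric(n_h)
    p_rr_h0 <- numeric(n_h)
    dwmax <- matrix(NA_real_, n_h, n_b)
    lo_h0 <- rep(1, n_h); hi_h0 <- rep(max(bc_grid), n_h)
    never <- logical(n_h)
    ok <- TRUE
    for (j in seq_len(n_h)) {
      params <- model_params(b = 2, c = 1, mu_e = mu_e, mu_a = mu_a,
                             h0 = h0_set[j])
      tab <- invasion_table(res, mutants, params)
      ok <- ok && all(tab$converged)
      aff <- dw_affine(tab)
      # mutants x grid matrix of fitness advantages, for the export table
      dw <- outer(aff$slope, bc_grid) + aff$intercept
      dwmax[j, ] <- apply(dw, 2L, max)
      ess_by_h0[j, ] <- dwmax[j, ] <= tol
      p_rr_h0[j] <- tab$p_rr[1L]
      # exact resist window {b : dw_m(b) <= tol for every mutant m}: each
      # dw is affine in b, so the window is an interval whose ends solve
      # dw = tol in closed form (no grid involved)
      eps <- 1e-9
      pos <- aff$slope > eps
      neg <- aff$slope < -eps
      flat <- !pos & !neg
      never[j] <- any(flat & aff$intercept > tol)
      if (any(pos))
        hi_h0[j] <- min((tol - aff$intercept[pos]) / aff$slope[pos])
      if (any(neg))
        lo_h0[j] <- max(1, (tol - aff$intercept[neg]) / aff$slope[neg])
      # tolerance-free critical ratio (ties resist exactly at dw = 0)
      open_ended <- (pos & aff$slope * max(bc_grid) + aff$intercept > tol) |
        (flat & aff$intercept > tol)
      thr_h0[j] <- if (any(open_ended)) NA_real_
        else max(1, ifelse(neg, -aff$intercept / aff$slope, -Inf))
    }
    lo_common <- max(lo_h0)
    hi_common <- min(hi_h0)
    common <- apply(ess_by_h0, 2L, all)
    ess_all <- any(common)
    cls <- if (all(p_rr_h0 >= 1 - eps_class)) "cooperator"
      else if (all(p_rr_h0 <= eps_class)) "defector"
      else "intermediate"
    rec[[i]] <- data.frame(
      code = rcode, bits = format(res), class = cls,
      ess_all_h0 = if (ok) ess_all else NA,
      min_bc_common = if (ess_all) min(bc_grid[common]) else NA_real_,
      max_bc_common = if (ess_all) max(bc_grid[common]) else NA_real_,
      window_lo = if (ess_all) lo_common else NA_real_,
      window_hi = if (ess_all) hi_common else NA_real_,
      threshold_max = if (anyNA(thr_h0)) NA_real_ else max(thr_h0),
      converged = ok,
      stringsAsFactors = FALSE)
    grid_rows[[i]] <- data.frame(
      code = rcode, h0 = rep(h0_set, each = n_b), bc = rep(bc_grid, n_h),
      is_ess = as.vector(t(ess_by_h0)), delta_w_max = as.vector(t(dwmax)),
      stringsAsFactors = FALSE)
    if (progress && i %% 32L == 0L) cat(".")
  }
  if (progress) cat("\n")
  records <- do.call(rbind, rec)
  grid <- do.call(rbind, grid_rows)
  grid <- grid[order(grid$code, grid$h0, grid$bc), ]
  summary <- list(
    n_residents = n_r,
    n_ess = sum(records$ess_all_h0, na.rm = TRUE),
    n_cooperator_ess = sum(records$ess_all_h0 &
                             records$class == "cooperator", na.rm = TRUE),
    n_defector_ess = sum(records$ess_all_h0 &
                           records$class == "defector", na.rm = TRUE),
    mu_e = mu_e, mu_a = mu_a, h0_set = h0_set,
    bc_range = range(bc_grid))
  structure(list(records = records, grid = grid, summary = summary),
            class = "ir_ess_scan")
}

#' @export
print.ir_ess_scan <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "<ess scan: %d residents, h0 in {%s}, b/c in [%g, %g], ",
    "mu_e=%g mu_a=%g>\n  ESS at all h0: %d  (cooperators %d, defectors %d)\n"),
    s$n_residents, paste(s$h0_set, collapse = ", "),
    s$bc_range[1L], s$bc_range[2L], s$mu_e, s$mu_a,
    s$n_ess, s$n_cooperator_ess, s$n_defector_ess))
  invisible(x)
}

#' Mutual-invasion (polymorphism) check
#'
#' Two strategies that can each invade the other coexist in a stable
#' polymorphism rather than replacing one another.
#'
#' @param r,m `ir_strategy` objects.
#' @param params an `ir_params`.
#' @param tol fitness tolerance.
#' @return logical.
#' @export
polymorphism_check <- function(r, m, params = model_params(),
                               tol = FITNESS_TOL) {
  if (encode_strategy(r) == encode_strategy(m)) return(FALSE)
  f1 <- invasion_fitness(r, m, params, tol)
  f2 <- invasion_fitness(m, r, params, tol)
  isTRUE(f1$invades) && isTRUE(f2$invades)
}
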