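# Root and flow utilities for polynomial 1-D dynamics dh/dt = f(h) on [0,1].
# The flow endpoint from h0 is the nearest root of f in the direction of
# sign(f(h0)); between consecutive roots f has constant sign, so this equals
# the limit of forward time-integration (no discretisation error).

POLY_ZERO_TOL <- 1e-13   # |coef| below this => term absent
ROOT_F_TOL    <- 1e-11   # |f(h)| below this => h counts as a root
EIG_TOL       <- 1e-8    # |f'(h*)| below this => marginal

poly_eval <- function(k, h) {
  out <- rep(0, length(h))
  for (i in rev(seq_along(k))) out <- out * h + k[i]
  out
}

poly_deriv <- function(k) {
  if (length(k) <= 1L) return(0)
  k[-1L] * seq_len(length(k) - 1L)
}

# All roots of the degree-<=3 polynomial k in [0,1].  f is monotone between
# its critical points, so bracketing on the partition {0, crit, 1} finds
# every sign-change root; tangent (double) roots are caught at the critical
# points and interval endpoints by the |f| tolerance.
poly_roots01 <- function(k) {
  f <- function(h) poly_eval(k, h)
  dk <- poly_deriv(k)
  crit <- numeric(0)
  if (length(dk) == 3L && abs(dk[3L]) > POLY_ZERO_TOL) {
    disc <- dk[2L]^2 - 4 * dk[3L] * dk[1L]
    if (disc >= 0) crit <- (-dk[2L] + c(-1, 1) * sqrt(disc)) / (2 * dk[3L])
  } else if (length(dk) >= 2L && abs(dk[2L]) > POLY_ZERO_TOL) {
    crit <- -dk[1L] / dk[2L]
  }
  breaks <- sort(unique(c(0, crit[crit > 0 & crit < 1], 1)))
  roots <- breaks[abs(f(breaks)) < ROOT_F_TOL]
  for (i in seq_len(length(breaks) - 1L)) {
    a <- breaks[i]; b <- breaks[i + 1L]
    if (f(a) * f(b) < 0) {
      r <- stats::uniroot(f, c(a, b), tol = 1e-15)$root
      roots <- c(roots, r)
    }
  }
  roots <- sort(roots)
  if (length(roots) > 1L) roots <- roots[c(TRUE, diff(roots) > 1e-9)]
  roots
}

# Endpoint of the forward flow of dh/dt = f(h) started at h0.
flow_endpoint <- function(k, h0) {
  if (all(abs(k) < POLY_ZERO_TOL))
    return(list(h = h0, marginal = TRUE, residual = 0))
  f0 <- poly_eval(k, h0)
  if (abs(f0) < ROOT_F_TOL)
    return(list(h = h0, marginal = NA, residual = abs(f0)))
  roots <- poly_roots01(k)
  if (f0 > 0) {
    ahead <- roots[roots > h0 + 1e-12]
    h <- if (length(ahead)) min(ahead) else 1
  } else {
    behind <- roots[roots < h0 - 1e-12]
    h <- if (length(behind)) max(behind) else 0
  }
  list(h = h, marginal = NA, residual = abs(poly_eval(k, h)))
}

stability_label <- function(lead_eig) {
  if (lead_eig < -EIG_TOL) "stable"
  else if (lead_eig <= EIG_TOL) "marginal"
  else "unstable"
}

new_equilibrium_result <- function(h_star, stable, converged, residual,
                                   steps, note = NULL) {
  structure(list(h_star = h_star, stable = stable, converged = converged,
                 residual = residual, steps = steps, note = note),
            class = "ir_equilibrium")
}

#' @export
print.ir_equilibrium <- function(x, ...) {
  cat(sprintf("<equilibrium h* = (%s)  %s%s  residual %.2e  steps %d>\n",
              paste(signif(x$h_star, 6), collapse = ", "), x$stable,
              if (x$converged) "" else "  NOT CONVERGED", x$residual,
              x$steps))
  invisible(x)
}

#' Long-run h-score of a monomorphic population
#'
#' Follows the deterministic dynamics `dh/dt = p(o) - h` forward from the
#' shared initial condition `params$h0` and reports the fixed point reached,
#' its stability (sign of the derivative slope there) and the residual.  The
#' default `"flow"` method evaluates the forward-flow limit exactly from the
#' polynomial roots (the endpoint is the nearest root in the direction of
#' motion, which is what time-stepping converges to); `"integrate"` runs an
#' adaptive explicit integrator and is kept as an independent cross-check.
#' A strategy whose derivative vanishes identically (e.g. image scoring
#' without errors) stays at `h0` and is reported as marginal.
#'
#' @inheritParams monomorphic_derivative
#' @param method `"flow"` (exact) or `"integrate"`.
#' @param tol convergence tolerance on `|dh/dt|` for the integrator.
#' @param t_max time budget for the integrator.
#' @return an `ir_equilibrium` with a single `h_star` coordinate.
#' @export
monomorphic_equilibrium <- function(s, params = model_params(),
                                    method = c("flow", "integrate"),
                                    tol = 1e-10, t_max = 1e6) {
  s <- as_strategy(s)
  method <- match.arg(method)
  k <- derivative_poly(s, params)
  if (method == "flow") {
    fe <- flow_endpoint(k, params$h0)
    slope <- poly_eval(poly_deriv(k), fe$h)
    stable <- if (isTRUE(fe$marginal)) "marginal" else stability_label(slope)
    return(new_equilibrium_result(c(h_rr = fe$h), stable, TRUE,
                                  fe$residual, 0L))
  }
  h <- params$h0; t <- 0; dt <- 0.05; steps <- 0L
  f <- function(x) poly_eval(k, x)
  while (t < t_max) {
    fh <- f(h)
    if (abs(fh) < tol) break
    # Heun with step-doubling error control
    repeat {
      h1 <- min(max(h + dt * fh, 0), 1)
      h2 <- min(max(h + dt * (fh + f(h1)) / 2, 0), 1)
      if (abs(h2 - h1) < 1e-9 || dt < 1e-8) break
      dt <- dt / 2
    }
    h <- h2; t <- t + dt; steps <- steps + 1L
    dt <- min(dt * 1.3, 1e3)
    if (steps > 2e6) break
  }
  # a slow algebraic approach that exhausts the budget still counts as the
  # endpoint only if the derivative is tiny; otherwise flag it
  converged <- abs(f(h)) < max(tol, 1e-8)
  slope <- poly_eval(poly_deriv(k), h)
  stable <- if (all(abs(k) < POLY_ZERO_TOL)) "marginal"
            else stability_label(slope)
  new_equilibrium_result(c(h_rr = h), stable, converged, abs(f(h)), steps)
}

#' Long-run h-scores with a rare mutant present
#'
#' The resident coordinate is autonomous, so it is equilibrated first (as in
#' the monomorphic case, from the same `h0`); the remaining two coupled
#' polynomial equations in `(h_mr, h_rm)` are then solved forward from
#' `(h0, h0)` with the resident h-score held at its equilibrium.  `h_rm`
#' is itself autonomous and solved by the exact flow method; `h_mr` obeys a
#' linear equation whose limit is reached in closed form whenever it is
#' contracting, with numerical integration of the coupled transient reserved
#' for the marginal cases.  Stability reports the leading eigenvalue of the
#' (triangular) Jacobian at the endpoint.
#'
#' @param resident,mutant `ir_strategy` objects.
#' @param params an `ir_params` (its `h0` is the shared initial condition).
#' @param tol convergence tolerance on the derivative norm.
#' @param t_max time budget for the transient integrator.
#' @return an `ir_equilibrium` whose `h_star` is `(h_rr, h_mr, h_rm)`.
#' @export
dimorphic_equilibrium <- function(resident, mutant, params = model_params(),
                                  tol = 1e-10, t_max = 1e6) {
  resident <- as_strategy(resident); mutant <- as_strategy(mutant)
  mono <- monomorphic_equilibrium(resident, params)
  r_star <- unname(mono$h_star[1L])
  out <- solve_dimorphic_batch(as.integer(resident), r_star,
                               matrix(as.integer(mutant), nrow = 1L),
                               params$h0, params$mu_e, params$mu_a,
                               tol, t_max)
  lead <- max(out[1L, "eig_x"], out[1L, "eig_y"])
  mono_slope <- poly_eval(poly_deriv(derivative_poly(resident, params)),
                          r_star)
  if (mono$stable != "marginal") lead <- max(lead, mono_slope)
  note <- if (out[1L, "cycle_flag"] > 0) "residual not decreasing" else NULL
  new_equilibrium_result(
    h_state(r_star, unname(out[1L, "h_mr"]), unname(out[1L, "h_rm"])),
    if (mono$stable == "marginal" && abs(lead) <= EIG_TOL) "marginal"
    else stability_label(lead),
    out[1L, "converged"] > 0 && mono$converged,
    max(out[1L, "residual"], mono$residual),
    as.integer(out[1L, "steps"]), note)
}
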