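## Between-season dynamics: progeny left at t = T found next season's
## infecting population, v_hat_{n+1} = v2_n(T). Iterating this map gives
## the resident's annual equilibrium density v_hat*.

#' Between-season map
#'
#' Maps a start-of-season free-parasite density to the end-of-season
#' progeny density `v2(T)` produced by one round of infection, which
#' becomes next season's starting density.
#'
#' @param v_hat Start-of-season density(ies) (>= 0).
#' @param params A [model_params()] object (its `v_init` is ignored).
#' @return End-of-season density(ies), same length as `v_hat`.
#' @examples
#' season_map(1, model_params())
#' @export
season_map <- function(v_hat, params) {
  stopifnot(inherits(params, "phv_params"))
  if (any(v_hat < 0)) stop("`v_hat` must be >= 0")
  vapply(v_hat, function(v) {
    if (v == 0) return(0)
    .v2_end_core(params$s_hat, params$t_l, params$mu, params$T,
                 params$tau, params$alpha, params$beta, params$delta,
                 v0 = v)
  }, numeric(1))
}

#' Parasite persistence criterion
#'
#' A single parasite introduced at the start of a season persists when the
#' progeny density it produces by the end of the season is at least the
#' single unit introduced, i.e. `season_map(1) >= 1` (the annual growth
#' factor of a rare parasite has modulus greater than unity).
#'
#' @param params A [model_params()] object.
#' @return A list with `growth_factor` (`season_map(1)`) and the logical
#'   `persists`.
#' @export
persistence_check <- function(params) {
  g <- season_map(1, params)
  list(growth_factor = g, persists = g >= 1)
}

#' Resident annual equilibrium
#'
#' Finds the fixed point `v_star` of the between-season map,
#' `season_map(v_star) = v_star`. When the persistence criterion fails only
#' the trivial fixed point exists and `v_star = 0` is returned. Otherwise
#' the nontrivial fixed point is bracketed (the map exceeds the identity at
#' small densities and saturates below it at large densities through host
#' depletion) and solved with Brent's method. When requested, local
#' stability of the annual dynamics is assessed from the map slope at the
#' fixed point, and an unstable fixed point triggers a search for a
#' period-2 cycle of the map, which is reported rather than hidden.
#'
#' @param params A [model_params()] object.
#' @param v_guess Optional positive warm-start guess for `v_star`.
#' @param tol Relative tolerance on the fixed-point residual.
#' @param diagnostics If `TRUE`, estimate the map slope at the fixed point
#'   and search for a period-2 cycle when the fixed point is unstable.
#' @return An object of class `phv_equilibrium`: list with `v_star`,
#'   `iterations`, `converged`, `residual`, `growth_factor`, and (with
#'   diagnostics) `slope`, `stable`, `period2` (a length-2 cycle or `NULL`).
#' @export
resident_equilibrium <- function(params, v_guess = NULL, tol = 1e-8,
                                 diagnostics = TRUE) {
  stopifnot(inherits(params, "phv_params"))
  g1 <- season_map(1, params)
  iters <- 1L
  res <- structure(list(v_star = 0, iterations = iters, converged = TRUE,
                        residual = 0, growth_factor = g1,
                        slope = NA_real_, stable = NA, period2 = NULL),
                   class = "phv_equilibrium")
  if (g1 < 1) return(res)
  h <- function(v) season_map(v, params) - v
  ## bracket: lo with map(lo) > lo, hi with map(hi) < hi
  lo <- 1; hi <- NULL
  if (!is.null(v_guess) && is.finite(v_guess) && v_guess > 1) {
    cand_lo <- max(1, v_guess / 4); cand_hi <- v_guess * 4
    iters <- iters + 2L
    if (h(cand_lo) > 0) lo <- cand_lo
    if (h(cand_hi) < 0) hi <- cand_hi
  }
  if (is.null(hi)) {
    hi <- max(10, lo * 10)
    expand <- 0L
    while (h(hi) > 0 && expand < 60L) {
      hi <- hi * 10
      expand <- expand + 1L
    }
    iters <- iters + expand + 1L
    if (expand >= 60L) {
      res$converged <- FALSE
      res$residual <- Inf
      res$v_star <- NA_real_
      return(res)
    }
  }
  r <- stats::uniroot(h, c(lo, hi), tol = max(hi * 1e-13, 1e-12))
  iters <- iters + r$iter
  v_star <- r$root
  residual <- abs(season_map(v_star, params) - v_star) / max(v_star, 1)
  res$v_star <- v_star
  res$iterations <- iters
  res$residual <- residual
  res$converged <- residual < tol
  if (diagnostics) {
    eps <- 1e-4 * v_star
    slope <- (season_map(v_star + eps, params) -
                season_map(v_star - eps, params)) / (2 * eps)
    res$slope <- slope
    res$stable <- abs(slope) < 1
    if (!res$stable) res$period2 <- .find_period2(params, v_star, hi)
  }
  res
}

## Search for a period-2 cycle of the annual map around an unstable fixed
## point: fixed points of map(map(v)) distinct from v_star.
.find_period2 <- function(params, v_star, hi) {
  m2 <- function(v) season_map(season_map(v, params), params) - v
  for (fac in c(1.05, 1.25, 2)) {
    a <- v_star * fac
    if (a < hi && sign(m2(a)) != sign(m2(hi))) {
      va <- stats::uniroot(m2, c(a, hi), tol = hi * 1e-10)$root
      if (abs(va - v_star) > 1e-6 * max(v_star, 1)) {
        vb <- season_map(va, params)
        return(c(va, vb))
      }
    }
  }
  NULL
}

#' @export
print.phv_equilibrium <- function(x, ...) {
  cat("Resident annual equilibrium\n")
  cat(sprintf("  v_star = %.8g (growth factor at v=1: %.6g)\n",
              x$v_star, x$growth_factor))
  cat(sprintf("  converged = %s, residual = %.3g, map evaluations = %d\n",
              x$converged, x$residual, x$iterations))
  if (!is.na(x$stable) && !x$stable)
    cat(sprintf("  WARNING: fixed point unstable (slope %.3g)%s\n", x$slope,
                if (!is.null(x$period2))
                  sprintf("; period-2 cycle near (%.4g, %.4g)",
                          x$period2[1], x$period2[2]) else ""))
  invisible(x)
}
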