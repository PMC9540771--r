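## Evolutionary invasion analysis for the incubation delay tau.
##
## A rare mutant experiences the season shaped by the resident at its
## annual equilibrium v_star: hosts are depleted by the resident's
## infection hazard alpha * v_star * exp(-delta t) in addition to
## background mortality. The mutant's end-of-season progeny density
## v2m(T), produced from initial density v1m(0), is the invasion fitness
## measure; the mutant invades when v2m(T) >= v1m(0).
##
## Per-capita fitness of a vanishingly rare mutant in that environment:
##   w(tau_m) = alpha_m * beta(tau_m) *
##              exp(-mu*tau_m - delta_m*(T - tau_m)) * I(T - tau_m),
##   I(u)     = int_0^u s_env(w) dw,
## with s_env the host density under resident-only depletion. Since s_env
## does not depend on tau_m, the selection gradient is available in closed
## form (given I and s_env):
##   dw/dtau_m = w * [delta_m - mu + beta'/beta - s_env(T-tau_m)/I(T-tau_m)].

#' Mutant trait set
#'
#' Builds the traits of an invading mutant, defaulting every trait to the
#' resident's (the baseline analysis varies only `tau_m`). When the
#' resident carries a trade-off and no explicit `beta_m` is given, the
#' mutant's progeny number is derived from the trade-off at `tau_m`.
#'
#' @param params Resident [model_params()].
#' @param tau_m,alpha_m,beta_m,delta_m Mutant traits; `NULL` means
#'   "same as resident" (for `beta_m`: derived from the trade-off if one
#'   is attached).
#' @return A `phv_traits` object.
#' @export
mutant_traits <- function(params, tau_m = NULL, alpha_m = NULL,
                          beta_m = NULL, delta_m = NULL) {
  stopifnot(inherits(params, "phv_params"))
  tau_m <- tau_m %||% params$tau
  if (is.null(beta_m)) {
    beta_m <- if (!is.null(params$tradeoff))
      beta_of_tau(params$tradeoff, tau_m) else params$beta
  }
  parasite_traits(tau = tau_m, alpha = alpha_m %||% params$alpha,
                  beta = beta_m, delta = delta_m %||% params$delta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mutant end-of-season progeny density
#'
#' Invasion fitness of a mutant introduced at density `v1m0` at the start
#' of a season in the environment set by the resident at density `v_star`.
#' Both the resident's depletion of hosts (`alpha * v_star`) and the
#' mutant's own self-shading (`alpha_m * v1m0`) enter the host hazard.
#' With `mutant` identical to the resident and `v_star = 0` this reduces
#' exactly to [season_v2_end()] with `v_init = v1m0`.
#'
#' @param params Resident [model_params()].
#' @param v_star Resident start-of-season equilibrium density (>= 0).
#' @param mutant A [mutant_traits()] object (default: resident traits).
#' @param v1m0 Initial mutant density (default 1, the invasion
#'   convention).
#' @return The scalar `v2m(T)`.
#' @export
mutant_v2_end <- function(params, v_star, mutant = NULL, v1m0 = 1) {
  stopifnot(inherits(params, "phv_params"), v_star >= 0, v1m0 >= 0)
  m <- mutant %||% mutant_traits(params)
  .v2_end_core(params$s_hat, params$t_l, params$mu, params$T,
               m$tau, m$alpha, m$beta, m$delta, v0 = v1m0,
               extra_a = params$alpha * v_star, extra_d = params$delta)
}

## Rare-mutant machinery in the environment set by v_star: engine with
## resident-only depletion plus closures for per-capita fitness, the
## analytic gradient factor psi and its derivative.
.mutant_machine <- function(params, v_star) {
  eng <- .season_engine(params$s_hat, params$t_l, params$mu,
                        haz_a = params$alpha * v_star,
                        haz_d = params$delta)
  p <- params
  w_pc <- function(tau_m) {
    if (tau_m >= p$T) return(0)
    bet <- if (!is.null(p$tradeoff)) beta_of_tau(p$tradeoff, tau_m) else p$beta
    p$alpha * bet * exp(-p$mu * tau_m - p$delta * (p$T - tau_m)) *
      .integrate_s(eng, p$T - tau_m)
  }
  psi <- function(tau_m) {
    u <- p$T - tau_m
    I <- .integrate_s(eng, u)
    bp <- .beta_logderiv(p$tradeoff, tau_m)
    p$delta - p$mu + bp - eng$s(u) / I
  }
  psi_prime <- function(tau_m) {
    u <- p$T - tau_m
    I <- .integrate_s(eng, u)
    su <- eng$s(u)
    dlb <- if (is.null(p$tradeoff)) 0 else -.beta_logderiv(p$tradeoff, tau_m)^2
    dlb + (eng$s_prime(u) * I - su^2) / I^2
  }
  list(eng = eng, w_pc = w_pc, psi = psi, psi_prime = psi_prime)
}

#' Selection gradient on the incubation delay
#'
#' Derivative of the rare-mutant invasion fitness `v2m(T)` with respect to
#' the mutant delay `tau_m`, evaluated at `tau_m = tau_r` in the
#' environment set by the resident at its equilibrium. A positive value
#' means selection for longer delays (lower virulence). The default is the
#' exact analytic derivative of the fitness expression; `method = "fd"`
#' uses a central finite difference with step `h = 1e-4 * max(1, tau_r)`
#' as an independent cross-check.
#'
#' @param tau_r Resident delay (0 < `tau_r` < T).
#' @param params [model_params()] (its `tau` is replaced by `tau_r`).
#' @param v_star Optional resident equilibrium density; computed with
#'   [resident_equilibrium()] when `NULL`.
#' @param method `"analytic"` (default) or `"fd"`.
#' @return The gradient value, with attributes `w_pc` (per-capita fitness
#'   at `tau_r`) and `v_star`.
#' @export
selection_gradient <- function(tau_r, params, v_star = NULL,
                               method = c("analytic", "fd")) {
  method <- match.arg(method)
  stopifnot(tau_r > 0, tau_r < params$T)
  p <- update_params(params, tau = tau_r)
  if (is.null(v_star))
    v_star <- resident_equilibrium(p, diagnostics = FALSE)$v_star
  mm <- .mutant_machine(p, v_star)
  g <- if (method == "analytic") {
    mm$w_pc(tau_r) * mm$psi(tau_r)
  } else {
    h <- 1e-4 * max(1, tau_r)
    (mm$w_pc(tau_r + h) - mm$w_pc(tau_r - h)) / (2 * h)
  }
  attr(g, "w_pc") <- mm$w_pc(tau_r)
  attr(g, "v_star") <- v_star
  g
}

#' Locate the singular virulence strategy
#'
#' Finds the delay `tau_star` at which the selection gradient vanishes,
#' recomputing the resident equilibrium for every candidate resident (the
#' selective environment depends on the resident trait). The search is
#' restricted to the sub-interval of `bracket` on which the resident
#' persists; if the gradient does not change sign there, a boundary
#' diagnosis is returned instead of a fabricated root. At the root, the
#' second derivative of mutant fitness classifies evolutionary stability
#' (ESS when negative), and the gradient's sign change across the root
#' classifies convergence stability.
#'
#' @param params A [model_params()] object.
#' @param bracket Search interval for `tau_star`; default
#'   `c(0.05, 0.98) * T`.
#' @param tol Absolute tolerance on `tau_star`.
#' @return An object of class `phv_singular` with fields `found`,
#'   `tau_star`, `gradient_at_star`, `second_derivative`, `is_ess`,
#'   `is_convergence_stable`, `v_star`, `persistence_window`,
#'   `environment` and, when no interior root exists, `direction`.
#' @export
find_singular_strategy <- function(params, bracket = NULL, tol = 1e-9) {
  stopifnot(inherits(params, "phv_params"))
  bracket <- bracket %||% (c(0.05, 0.98) * params$T)
  stopifnot(length(bracket) == 2, bracket[1] > 0, bracket[2] < params$T,
            bracket[1] < bracket[2])
  env_desc <- list(T = params$T, t_l = params$t_l,
                   tradeoff = if (is.null(params$tradeoff)) "none"
                   else attr(params$tradeoff, "kind"))
  out <- structure(list(found = FALSE, tau_star = NA_real_,
                        gradient_at_star = NA_real_,
                        second_derivative = NA_real_,
                        is_ess = NA, is_convergence_stable = NA,
                        v_star = NA_real_, persistence_window = NULL,
                        direction = NULL, environment = env_desc),
                   class = "phv_singular")

  pers <- function(tr) season_map(1, update_params(params, tau = tr)) - 1
  win <- .persistence_window(pers, bracket)
  if (is.null(win)) {
    out$direction <- "resident not persistent anywhere in bracket"
    return(out)
  }
  out$persistence_window <- win

  cache <- new.env(parent = emptyenv())
  cache$last <- NULL
  eq_at <- function(tr) {
    key <- sprintf("t%.12e", tr)
    if (is.null(cache[[key]])) {
      eq <- resident_equilibrium(update_params(params, tau = tr),
                                 v_guess = cache$last, diagnostics = FALSE)
      cache$last <- if (eq$v_star > 0) eq$v_star else cache$last
      cache[[key]] <- eq$v_star
    }
    cache[[key]]
  }
  G <- function(tr) {
    vs <- eq_at(tr)
    p <- update_params(params, tau = tr)
    mm <- .mutant_machine(p, vs)
    mm$w_pc(tr) * mm$psi(tr)
  }
  glo <- G(win[1]); ghi <- G(win[2])
  if (sign(glo) == sign(ghi)) {
    out$direction <- if (glo > 0)
      "selection gradient positive throughout (selection for longer tau)"
    else "selection gradient negative throughout (selection for shorter tau)"
    return(out)
  }
  r <- stats::uniroot(G, lower = win[1], upper = win[2], tol = tol,
                      f.lower = glo, f.upper = ghi)
  tau_star <- r$root
  v_star <- eq_at(tau_star)
  p_star <- update_params(params, tau = tau_star)
  mm <- .mutant_machine(p_star, v_star)
  w <- mm$w_pc(tau_star)
  psi <- mm$psi(tau_star)
  d2 <- w * (psi^2 + mm$psi_prime(tau_star))
  dd <- min(0.02 * max(1, tau_star),
            0.45 * (tau_star - win[1]), 0.45 * (win[2] - tau_star))
  cs <- G(tau_star - dd) > 0 && G(tau_star + dd) < 0
  out$found <- TRUE
  out$tau_star <- tau_star
  out$gradient_at_star <- w * psi
  out$second_derivative <- d2
  out$is_ess <- d2 < 0
  out$is_convergence_stable <- cs
  out$v_star <- v_star
  out
}

## Sub-interval of `bracket` on which pers() >= 0, located by a coarse scan
## plus bisection of the boundary crossings.
.persistence_window <- function(pers, bracket, n_scan = 9L) {
  grid <- seq(bracket[1], bracket[2], length.out = n_scan)
  pv <- vapply(grid, pers, numeric(1))
  ok <- pv >= 0
  if (!any(ok)) return(NULL)
  i1 <- which(ok)[1]; i2 <- rev(which(ok))[1]
  lo <- grid[i1]; hi <- grid[i2]
  margin <- 1e-4 * (bracket[2] - bracket[1])
  if (i1 > 1)
    lo <- stats::uniroot(pers, c(grid[i1 - 1], grid[i1]), tol = 1e-6)$root +
      margin
  if (i2 < n_scan)
    hi <- stats::uniroot(pers, c(grid[i2], grid[i2 + 1]), tol = 1e-6)$root -
      margin
  c(lo, hi)
}

#' @export
print.phv_singular <- function(x, ...) {
  cat("Singular virulence strategy\n")
  cat(sprintf("  environment: T = %.4g, t_l = %.4g, trade-off = %s\n",
              x$environment$T, x$environment$t_l, x$environment$tradeoff))
  if (x$found) {
    cat(sprintf("  tau_star = %.6g (gradient %.3g)\n", x$tau_star,
                x$gradient_at_star))
    cat(sprintf("  ESS: %s (d2 fitness = %.4g); convergence stable: %s\n",
                x$is_ess, x$second_derivative, x$is_convergence_stable))
    cat(sprintf("  resident equilibrium v_star = %.6g\n", x$v_star))
  } else {
    cat("  no interior singular strategy: ", x$direction, "\n", sep = "")
  }
  invisible(x)
}

#' Pairwise invasibility surface
#'
#' Per-capita annual growth (minus one) of a rare mutant with delay
#' `tau_mut` in the environment of a resident with delay `tau_res` at its
#' equilibrium. Entries are `v2m(T)/v1m(0) - 1` in the vanishing-density
#' limit: positive entries mean the mutant invades, the diagonal is
#' neutral (zero to the equilibrium tolerance), and the column at
#' `tau_res = tau_star` is nowhere positive when `tau_star` is an ESS.
#' Residents that do not persist get the parasite-free environment
#' (`v_star = 0`).
#'
#' @param params A [model_params()] object.
#' @param tau_res,tau_mut Grids of resident and mutant delays in (0, T).
#' @return A matrix (rows = `tau_mut`, columns = `tau_res`) of growth
#'   excess values, with the grids as dimnames.
#' @export
pip_grid <- function(params, tau_res, tau_mut = tau_res) {
  stopifnot(all(tau_res > 0), all(tau_res < params$T),
            all(tau_mut > 0), all(tau_mut < params$T))
  out <- matrix(NA_real_, nrow = length(tau_mut), ncol = length(tau_res),
                dimnames = list(mutant = sprintf("%.6g", tau_mut),
                                resident = sprintf("%.6g", tau_res)))
  for (j in seq_along(tau_res)) {
    p <- update_params(params, tau = tau_res[j])
    vs <- resident_equilibrium(p, diagnostics = FALSE)$v_star
    mm <- .mutant_machine(p, vs)
    out[, j] <- vapply(tau_mut, mm$w_pc, numeric(1)) - 1
  }
  out
}
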