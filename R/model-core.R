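## Within-season solution of the resident system.
##
## States over one season of length T:
##   s(t)   susceptible hosts, s(0) = 0, fed by emergence at rate s_hat*g(t),
##          drained by background death mu and infection hazard alpha*v1(t);
##   v1(t)  infecting free parasites, pure exponential decay v_init*exp(-delta t)
##          (losses to transmission are neglected);
##   v2(t)  progeny released by killed hosts, produced with delay tau and
##          decaying at rate delta.
##
## The integrating-factor solution used throughout is
##   s(t)  = (s_hat/t_l) * exp(-H(t)) * int_0^{min(t, t_l)} exp(H(x)) dx,
##   H(t)  = mu*t + sum_i (a_i/d_i) * (1 - exp(-d_i t)),
## where each (a_i, d_i) pair is one free-parasite hazard component
## a_i*exp(-d_i t) (the resident's alpha*v1, plus, in invasion analyses,
## the mutant's own alpha_m*v1m). Progeny accumulate as
##   v2(t) = alpha*beta*v_init * exp(-mu*tau - delta*(t - tau)) *
##           int_0^{t - tau} s(w) dw,                      t >= tau,
## which covers both regimes (release window ending before or after the
## emergence period): the outer integral is split at t_l, where the closed
## form of s changes branch.

#' Per-capita host emergence rate
#'
#' Uniform emergence density: hosts emerge at rate `1/t_l` from the start
#' of the season until `t = t_l`, and not thereafter. Integrates to one
#' over any season at least `t_l` long.
#'
#' @param t Season-local time(s), >= 0.
#' @param t_l Length of the emergence period (> 0).
#' @return Per-capita emergence rate(s) (1/time).
#' @examples
#' emergence_rate(0.5, t_l = 1)
#' @export
emergence_rate <- function(t, t_l) {
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be finite and >= 0")
  if (!is.numeric(t_l) || length(t_l) != 1 || !is.finite(t_l) || t_l <= 0)
    stop("`t_l` must be a positive scalar")
  ifelse(t <= t_l, 1 / t_l, 0)
}

#' Free-parasite density v1(t)
#'
#' Start-of-season parasites decay exponentially in the environment;
#' removal through transmission is neglected.
#'
#' @param t Season-local time(s), >= 0.
#' @param v_init Start-of-season density `v1(0)` (>= 0).
#' @param delta Decay rate (1/time, >= 0).
#' @return Density `v_init * exp(-delta * t)`.
#' @export
free_parasite_density <- function(t, v_init, delta) {
  if (any(t < 0)) stop("`t` must be >= 0")
  v_init * exp(-delta * t)
}

## Cumulative integral of f tabulated on a uniform grid x (odd length).
## Simpson increments on node pairs for even indices; odd indices filled by
## integrating the local quadratic through the three surrounding nodes.
## Global accuracy O(h^4).
.cumquad <- function(x, f) {
  n <- length(x)
  h <- x[2] - x[1]
  out <- numeric(n)
  ie <- seq(3, n, by = 2)                      # even-numbered subinterval ends
  simp <- (h / 3) * (f[ie - 2] + 4 * f[ie - 1] + f[ie])
  out[ie] <- cumsum(simp)
  io <- seq(2, n - 1, by = 2)                  # odd nodes
  out[io] <- out[io - 1] + (h / 12) * (5 * f[io] + 8 * f[io - 1] - f[io + 1])
  out
}

## Gauss-Legendre nodes/weights on [0, 1], cached.
.phv_env <- new.env(parent = emptyenv())
.gl01 <- function(n = 10) {
  key <- paste0("gl", n)
  if (is.null(.phv_env[[key]])) {
    g <- pracma::gaussLegendre(n, 0, 1)
    .phv_env[[key]] <- g
  }
  .phv_env[[key]]
}

## Build the within-season engine for host density under a set of
## free-parasite hazard components a_i * exp(-d_i * t).
## Returns closures H(t), s(t) and the antiderivative data.
.season_engine <- function(s_hat, t_l, mu, haz_a, haz_d, n_grid = 2001L) {
  keep <- haz_a > 0
  haz_a <- haz_a[keep]; haz_d <- haz_d[keep]
  H <- function(t) {
    out <- mu * t
    for (i in seq_along(haz_a))
      out <- out + (haz_a[i] / haz_d[i]) * (1 - exp(-haz_d[i] * t))
    out
  }
  lambda <- function(t) {
    out <- rep(0, length(t))
    for (i in seq_along(haz_a)) out <- out + haz_a[i] * exp(-haz_d[i] * t)
    out
  }
  if (n_grid %% 2L == 0L) n_grid <- n_grid + 1L
  Htl <- H(t_l)
  if (Htl < 500) {
    ## fast path: shared tabulated antiderivative (no under/overflow here)
    x <- seq(0, t_l, length.out = n_grid)
    Cgrid <- .cumquad(x, exp(H(x) - Htl))      # int_0^w exp(H(x) - H(t_l)) dx
    Cfun <- stats::splinefun(x, Cgrid, method = "hyman")
    s <- function(w) {
      Cw <- pmax(Cfun(pmin(w, t_l)), 0)
      (s_hat / t_l) * exp(Htl - H(w)) * Cw
    }
  } else {
    ## extreme-hazard path: per-point quadrature of exp(H(x) - H(w)),
    ## whose integrand lies in (0, 1] for x <= w, so it never overflows
    s <- function(w) {
      vapply(w, function(wi) {
        up <- min(wi, t_l)
        if (up <= 0) return(0)
        Hw <- H(wi)
        val <- stats::integrate(function(x) exp(H(x) - Hw), 0, up,
                                rel.tol = 1e-10, subdivisions = 500L)$value
        (s_hat / t_l) * val
      }, numeric(1))
    }
  }
  s_prime <- function(w) {                     # ds/dw from the ODE itself
    src <- ifelse(w <= t_l, s_hat / t_l, 0)
    src - (mu + lambda(w)) * s(w)
  }
  list(H = H, s = s, s_prime = s_prime, lambda = lambda,
       t_l = t_l, s_hat = s_hat, mu = mu)
}

## int_0^upper s(w) dw by composite Gauss-Legendre, split at the emergence
## kink t_l. Panels are fixed so the quadrature is smooth in parameters.
.integrate_s <- function(eng, upper, panels = 8L, gl_n = 10L) {
  if (upper <= 0) return(0)
  gl <- .gl01(gl_n)
  seg <- function(a, b) {
    if (b <= a) return(0)
    brk <- seq(a, b, length.out = panels + 1L)
    w <- diff(brk)
    tot <- 0
    for (k in seq_len(panels)) {
      xs <- brk[k] + w[k] * gl$x
      tot <- tot + w[k] * sum(gl$w * eng$s(xs))
    }
    tot
  }
  b1 <- min(upper, eng$t_l)
  seg(0, b1) + seg(eng$t_l, upper)
}

## End-of-season progeny density for a parasite with traits
## (tau, alpha, beta, delta) and initial density v0, infecting a host
## cohort that is also depleted by the extra hazard components in
## haz_a/haz_d (e.g. the resident's alpha * v_star in invasion analyses).
## Per-capita version obtained with v0 = 0 shading (see .mutant_machine).
.v2_end_core <- function(s_hat, t_l, mu, T, tau, alpha, beta, delta, v0,
                         extra_a = numeric(), extra_d = numeric(),
                         shade = TRUE) {
  if (tau >= T || beta <= 0 || v0 < 0) return(0)
  a_self <- if (shade) alpha * v0 else 0
  eng <- .season_engine(s_hat, t_l, mu,
                        haz_a = c(extra_a, a_self),
                        haz_d = c(extra_d, delta))
  I <- .integrate_s(eng, T - tau)
  alpha * beta * v0 * exp(-mu * tau - delta * (T - tau)) * I
}

#' Susceptible host density s(t)
#'
#' Exact integrating-factor solution of the host equation: emergence at
#' rate `s_hat * g(t, t_l)`, losses to background mortality `mu` and to
#' infection at hazard `alpha * v1(t)` with `v1(t) = v_init exp(-delta t)`.
#' `s(0) = 0`; the solution is continuous at `t = t_l`.
#'
#' @param t Season-local time(s) in `[0, T]`.
#' @param params A [model_params()] object.
#' @return Host density(ies) at `t`.
#' @export
susceptible_density <- function(t, params) {
  stopifnot(inherits(params, "phv_params"))
  if (any(t < 0) || any(t > params$T)) stop("`t` must lie in [0, T]")
  eng <- .season_engine(params$s_hat, params$t_l, params$mu,
                        haz_a = params$alpha * params$v_init,
                        haz_d = params$delta)
  eng$s(t)
}

#' End-of-season progeny density v2(T)
#'
#' The density of new parasites present at the end of the season, the
#' quantity iterated across seasons and the parasite's seasonal fitness.
#' Computed as `alpha * beta * v_init * exp(-mu*tau - delta*(T - tau))`
#' times the integral of the host density over the infection window
#' `[0, T - tau]`; the integral is split at `t_l`, which is exactly the
#' regime distinction between release windows that do (`tau < T - t_l`)
#' and do not (`tau > T - t_l`) extend past the emergence period.
#' Parasites that have not killed their host by the end of the season
#' release no progeny, so `tau >= T` gives 0 (with attribute
#' `censored = TRUE`).
#'
#' @param params A [model_params()] object.
#' @return The scalar `v2(T)` (parasites, >= 0).
#' @examples
#' season_v2_end(model_params())
#' @export
season_v2_end <- function(params) {
  stopifnot(inherits(params, "phv_params"))
  if (params$tau >= params$T) {
    out <- 0
    attr(out, "censored") <- TRUE
    return(out)
  }
  .v2_end_core(params$s_hat, params$t_l, params$mu, params$T,
               params$tau, params$alpha, params$beta, params$delta,
               v0 = params$v_init)
}

#' Within-season trajectory
#'
#' Evaluates the analytic within-season solution on a regular time grid.
#'
#' @param params A [model_params()] object.
#' @param n Number of grid points on `[0, T]`.
#' @return A tibble with columns `t`, `s`, `v1`, `v2`, and attribute
#'   `v2_end` equal to the final `v2` value.
#' @export
season_trajectory <- function(params, n = 501L) {
  stopifnot(inherits(params, "phv_params"), n >= 2)
  tt <- seq(0, params$T, length.out = n)
  eng <- .season_engine(params$s_hat, params$t_l, params$mu,
                        haz_a = params$alpha * params$v_init,
                        haz_d = params$delta)
  s <- eng$s(tt)
  v1 <- free_parasite_density(tt, params$v_init, params$delta)
  gl <- .gl01(5L)
  v2 <- numeric(n)
  acc <- 0                                     # cumulative int_0^{t-tau} s dw
  prev <- 0
  pref <- params$alpha * params$beta * params$v_init * exp(-params$mu * params$tau)
  for (i in seq_len(n)) {
    up <- tt[i] - params$tau
    if (up <= 0) next
    h <- up - prev
    xs <- prev + h * gl$x
    acc <- acc + h * sum(gl$w * eng$s(xs))
    prev <- up
    v2[i] <- pref * exp(-params$delta * (tt[i] - params$tau)) * acc
  }
  out <- tibble::tibble(t = tt, s = s, v1 = v1, v2 = v2)
  attr(out, "v2_end") <- v2[n]
  out
}
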