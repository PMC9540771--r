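## Independent numerical check of the analytic within-season solution.
##
## The delay system is converted exactly to a plain ODE by carrying
## time-shifted copies of the lagged states: sl(t) = s(t - tau) obeys the
## same host equation driven by the shifted emergence pulse and the shifted
## free-parasite density v1l(t) = v1(t - tau), which switches on at
## t = tau. No delay-history interpolation is needed, so the solver's full
## adaptive accuracy applies. Integration proceeds piecewise between the
## forcing discontinuities (t_l, the delays, and their sums), restarting
## the solver and applying the lag-state resets at segment boundaries.

## Piecewise integration over segments split at `breaks`; `resets` is a
## list of (time, values) applied to the state at matching segment starts.
.ode_segments <- function(y0, deriv, T_end, grid_size, breaks, resets,
                          rtol, atol, hmax) {
  brk <- sort(unique(breaks[breaks > 0 & breaks < T_end]))
  seg_pts <- c(0, brk, T_end)
  times_all <- sort(unique(c(seq(0, T_end, length.out = grid_size + 1),
                             brk)))
  y <- y0
  out <- NULL
  for (k in seq_len(length(seg_pts) - 1L)) {
    a <- seg_pts[k]; b <- seg_pts[k + 1L]
    for (r in resets)
      if (abs(a - r$time) < 1e-14) y[names(r$values)] <- r$values
    tt <- times_all[times_all >= a & times_all <= b]
    sol <- deSolve::ode(y, tt, deriv, parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol, hmax = hmax,
                        maxsteps = 1e5)
    y <- sol[nrow(sol), -1]
    out <- if (is.null(out)) sol else rbind(out, sol[-1, , drop = FALSE])
  }
  out
}

#' Numerical within-season oracle
#'
#' Integrates the resident within-season system directly with
#' [deSolve::ode()] (lsoda), treating the delayed progeny-production term
#' through exact time-shifted companion states. Used as an independent
#' check of the closed-form solution in [season_v2_end()] and
#' [susceptible_density()]; the two agree to the solver tolerance.
#'
#' @param params A [model_params()] object.
#' @param grid_size Number of output intervals on `[0, T]` (>= 1000); also
#'   bounds the solver's maximum internal step.
#' @param rtol,atol Solver tolerances.
#' @return A tibble with columns `t`, `s`, `v1`, `v2` and attribute
#'   `v2_end`.
#' @export
season_oracle <- function(params, grid_size = 1e4, rtol = 1e-10,
                          atol = NULL) {
  stopifnot(inherits(params, "phv_params"))
  if (grid_size < 1e3) stop("`grid_size` must be >= 1000")
  p <- params
  if (is.null(atol))
    atol <- 1e-12 * max(p$s_hat, p$v_init, 1)
  y0 <- c(s = 0, v1 = p$v_init, sl = 0, v1l = 0, v2 = 0)
  deriv <- function(t, y, parms) {
    g  <- if (t <= p$t_l) 1 / p$t_l else 0
    gl <- if (t > p$tau && (t - p$tau) <= p$t_l) 1 / p$t_l else 0
    ds   <- p$s_hat * g - p$mu * y[1] - p$alpha * y[1] * y[2]
    dv1  <- -p$delta * y[2]
    dsl  <- p$s_hat * gl - p$mu * y[3] - p$alpha * y[3] * y[4]
    dv1l <- -p$delta * y[4]
    dv2  <- p$alpha * p$beta * exp(-p$mu * p$tau) * y[3] * y[4] -
      p$delta * y[5]
    list(c(ds, dv1, dsl, dv1l, dv2))
  }
  resets <- if (p$tau < p$T)
    list(list(time = p$tau, values = c(v1l = p$v_init))) else list()
  sol <- .ode_segments(y0, deriv, p$T, grid_size,
                       breaks = c(p$t_l, p$tau, p$tau + p$t_l),
                       resets = resets, rtol = rtol, atol = atol,
                       hmax = p$T / 100)
  neg <- min(sol[, c("s", "v1", "v2")])
  if (neg < -atol * 1e3 - 1e-8 * max(p$s_hat, p$v_init))
    stop("oracle produced negative densities beyond tolerance")
  out <- tibble::tibble(t = sol[, "time"], s = sol[, "s"],
                        v1 = sol[, "v1"], v2 = sol[, "v2"])
  attr(out, "v2_end") <- out$v2[nrow(out)]
  out
}

## Oracle for the resident + rare-mutant system. The mutant has its own
## traits and initial density v1m0; the resident starts at v_star. Needs
## shifted copies of s for both delays, each paired with shifted copies of
## both free-parasite densities. Returns end-of-season v2 and v2m.
.mutant_oracle <- function(params, v_star, mutant, v1m0 = 1,
                           grid_size = 1e4, rtol = 1e-10) {
  p <- params
  m <- mutant
  atol <- 1e-12 * max(p$s_hat, v_star, v1m0, 1)
  ## y: s, v1, v1m, slr, v1lr, v1mlr, slm, v1lm, v1mlm, v2, v2m
  y0 <- c(s = 0, v1 = v_star, v1m = v1m0,
          slr = 0, v1lr = 0, v1mlr = 0,
          slm = 0, v1lm = 0, v1mlm = 0,
          v2 = 0, v2m = 0)
  deriv <- function(t, y, parms) {
    g   <- if (t <= p$t_l) 1 / p$t_l else 0
    glr <- if (t > p$tau && (t - p$tau) <= p$t_l) 1 / p$t_l else 0
    glm <- if (t > m$tau && (t - m$tau) <= p$t_l) 1 / p$t_l else 0
    haz  <- function(v1, v1m) p$alpha * v1 + m$alpha * v1m
    ds    <- p$s_hat * g - p$mu * y[1] - haz(y[2], y[3]) * y[1]
    dslr  <- p$s_hat * glr - p$mu * y[4] - haz(y[5], y[6]) * y[4]
    dslm  <- p$s_hat * glm - p$mu * y[7] - haz(y[8], y[9]) * y[7]
    dv2   <- p$alpha * p$beta * exp(-p$mu * p$tau) * y[4] * y[5] -
      p$delta * y[10]
    dv2m  <- m$alpha * m$beta * exp(-p$mu * m$tau) * y[7] * y[9] -
      m$delta * y[11]
    list(c(ds, -p$delta * y[2], -m$delta * y[3],
           dslr, -p$delta * y[5], -m$delta * y[6],
           dslm, -p$delta * y[8], -m$delta * y[9],
           dv2, dv2m))
  }
  resets <- list()
  if (p$tau < p$T)
    resets <- c(resets, list(list(time = p$tau,
                                  values = c(v1lr = v_star, v1mlr = v1m0))))
  if (m$tau < p$T)
    resets <- c(resets, list(list(time = m$tau,
                                  values = c(v1lm = v_star, v1mlm = v1m0))))
  sol <- .ode_segments(y0, deriv, p$T, grid_size,
                       breaks = c(p$t_l, p$tau, m$tau, p$tau + p$t_l,
                                  m$tau + p$t_l),
                       resets = resets, rtol = rtol, atol = atol,
                       hmax = p$T / 100)
  nr <- nrow(sol)
  list(v2_end = sol[nr, "v2"], v2m_end = sol[nr, "v2m"])
}
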