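## Individual-based stochastic validator.
##
## Event-level realisation of the same seasonal process at reduced
## population scale: n_hosts = s_hat / c hosts with transmission rate
## scaled up to c * alpha, which leaves every per-capita rate of the
## deterministic model unchanged (the model is invariant under
## (s_hat, alpha, v_hat) -> (s_hat/c, c*alpha, v_hat/c)). Within a season
## the infection hazard uses the deterministic free-parasite density
## v_init * exp(-delta * t) -- exact under the model's assumption that
## transmission losses of free parasites are negligible -- so no
## parasite-count bookkeeping is needed during the season.

#' Configuration for the individual-based validator
#'
#' @param params A [model_params()] object holding the full-scale
#'   parameters (rates `mu`, `delta`, `tau`, `beta` and phenology `t_l`,
#'   `T` are used as-is; `s_hat`, `alpha` and `v_init` are rescaled).
#' @param n_hosts Number of simulated hosts (>= 100); the scale factor is
#'   `c = s_hat / n_hosts`.
#' @param v_init Full-scale start-of-season parasite density; the
#'   simulation uses `v_init / c`. Defaults to `params$s_hat` (one
#'   parasite per host at full scale).
#' @param seed Integer seed; replicate `r` of [ibm_replicates()] uses
#'   `seed + r`.
#' @param n_replicates Number of replicate realisations.
#' @return An object of class `phv_ibm_config`.
#' @export
ibm_config <- function(params, n_hosts = 1e4, v_init = NULL, seed = 1L,
                       n_replicates = 50L) {
  stopifnot(inherits(params, "phv_params"), n_hosts >= 100)
  if (abs(params$beta - round(params$beta)) > 1e-9)
    stop("the individual-based model requires a whole-number `beta`")
  v_init <- v_init %||% params$s_hat
  c_scale <- params$s_hat / n_hosts
  structure(list(params = params, n_hosts = as.integer(n_hosts),
                 c_scale = c_scale,
                 alpha_ibm = params$alpha * c_scale,
                 v_init_ibm = v_init / c_scale,
                 seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates)),
            class = "phv_ibm_config")
}

#' Sample host emergence times
#'
#' Emergence times are i.i.d. uniform on `[0, t_l]`, matching the
#' deterministic emergence pulse.
#'
#' @param n Number of hosts.
#' @param t_l Emergence period length (> 0).
#' @param seed Optional seed; when given, the global RNG state is
#'   restored on exit so the draw is reproducible and side-effect free.
#' @return A numeric vector of `n` emergence times.
#' @export
sample_emergence_times <- function(n, t_l, seed = NULL) {
  stopifnot(n >= 1, t_l > 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  stats::runif(n, 0, t_l)
}

#' Simulate one season of the individual-based model
#'
#' Each host emerges at a uniform time, then faces competing risks of
#' background death (rate `mu`) and infection (time-varying hazard
#' `alpha_ibm * v_init_ibm * exp(-delta * t)`, sampled exactly by
#' inverting the integrated hazard). An infected host is killed
#' `tau` after infection and releases `beta` progeny -- unless background
#' mortality strikes first or the season ends, in which case nothing is
#' released. Each released parasite survives to the end of the season
#' independently with probability `exp(-delta * (T - release time))`.
#'
#' @param cfg An [ibm_config()] object.
#' @param seed Seed for this realisation (default `cfg$seed`).
#' @return An object of class `phv_ibm`: list with `events` (one row per
#'   host: emergence, background-death, infection and release times,
#'   progeny surviving) and the integer `v2_end_count`.
#' @export
simulate_season_ibm <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "phv_ibm_config"))
  p <- cfg$params
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- cfg$n_hosts
  a <- cfg$alpha_ibm * cfg$v_init_ibm      # hazard scale at t = 0
  emerge <- stats::runif(n, 0, p$t_l)
  t_bg <- if (p$mu > 0) emerge + stats::rexp(n, p$mu) else rep(Inf, n)
  ## exact inversion of the integrated infection hazard
  ## Lambda(e, t) = a * (exp(-delta e) - exp(-delta t)) / delta
  E <- stats::rexp(n)
  arg <- exp(-p$delta * emerge) - p$delta * E / a
  t_inf <- ifelse(arg > 0, -log(pmax(arg, .Machine$double.xmin)) / p$delta, Inf)
  t_inf[t_inf < emerge] <- emerge[t_inf < emerge]   # numerical guard
  infected <- t_inf < pmin(t_bg, p$T)
  t_inf[!infected] <- NA_real_
  t_rel <- t_inf + p$tau
  released <- infected & !is.na(t_rel) & t_rel <= p$T & t_rel < t_bg
  n_surv <- integer(n)
  if (any(released)) {
    pr <- exp(-p$delta * (p$T - t_rel[released]))
    n_surv[released] <- stats::rbinom(sum(released), round(p$beta), pr)
  }
  events <- tibble::tibble(
    host = seq_len(n), emergence = emerge, t_background = t_bg,
    t_infection = t_inf,
    t_release = ifelse(released, t_rel, NA_real_),
    released = released, progeny_surviving = n_surv)
  structure(list(events = events, v2_end_count = sum(n_surv),
                 n_infected = sum(infected), n_released = sum(released),
                 seed = seed, config = cfg),
            class = "phv_ibm")
}

#' Replicate individual-based realisations
#'
#' Runs `cfg$n_replicates` independent realisations (replicate `r` seeded
#' with `cfg$seed + r`) and summarises the end-of-season progeny counts
#' against the deterministic prediction at the same reduced scale.
#'
#' @param cfg An [ibm_config()] object.
#' @return A list with `replicates` (tibble: replicate, seed, n_infected,
#'   n_released, v2_end_count), `mean`, `se`, `deterministic` (the
#'   matching [season_v2_end()] value) and `z` (standardised deviation of
#'   the mean from the deterministic value).
#' @export
ibm_replicates <- function(cfg) {
  stopifnot(inherits(cfg, "phv_ibm_config"))
  rows <- lapply(seq_len(cfg$n_replicates), function(r) {
    sim <- simulate_season_ibm(cfg, seed = cfg$seed + r)
    tibble::tibble(replicate = r, seed = cfg$seed + r,
                   n_infected = sim$n_infected,
                   n_released = sim$n_released,
                   v2_end_count = sim$v2_end_count)
  })
  reps <- do.call(rbind, rows)
  p <- cfg$params
  det <- season_v2_end(model_params(
    s_hat = cfg$n_hosts, t_l = p$t_l, mu = p$mu, tau = p$tau,
    alpha = cfg$alpha_ibm, beta = p$beta, delta = p$delta,
    T = p$T, v_init = cfg$v_init_ibm))
  m <- mean(reps$v2_end_count)
  se <- stats::sd(reps$v2_end_count) / sqrt(nrow(reps))
  list(replicates = reps, mean = m, se = se,
       deterministic = as.numeric(det),
       z = (m - as.numeric(det)) / se)
}
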