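#' Host parameters
#'
#' Describes one seasonal host cohort: `s_hat` hosts emerge over the first
#' `t_l` time units of the season and die at per-capita background rate `mu`.
#' Hosts have non-overlapping generations and live at most one season.
#'
#' @param s_hat Emerging host cohort size (hosts, > 0).
#' @param t_l Length of the host emergence period (time, > 0).
#' @param mu Per-capita background host death rate (1/time, >= 0).
#' @return An object of class `phv_host`.
#' @examples
#' host_params(s_hat = 1e8, t_l = 1, mu = 0.5)
#' @export
host_params <- function(s_hat = 1e8, t_l = 1, mu = 0.5) {
  stopifnot(is.numeric(s_hat), length(s_hat) == 1, is.finite(s_hat),
            is.numeric(t_l), length(t_l) == 1, is.finite(t_l),
            is.numeric(mu), length(mu) == 1, is.finite(mu))
  if (s_hat <= 0) stop("`s_hat` must be > 0")
  if (t_l <= 0) stop("`t_l` must be > 0")
  if (mu < 0) stop("`mu` must be >= 0")
  structure(list(s_hat = s_hat, t_l = t_l, mu = mu), class = "phv_host")
}

#' Parasite traits
#'
#' Traits of one obligate-killer parasite strain: the incubation delay `tau`
#' between infection and parasite-induced host death (the inverse of
#' virulence), the transmission rate `alpha`, the number `beta` of progeny
#' released when the host is killed, and the environmental decay rate
#' `delta` of free-living parasites. `beta` may instead be tied to `tau`
#' through a transmission-virulence trade-off created with
#' [tradeoff_function()], in which case the realised progeny number is
#' `beta_of_tau(tradeoff, tau)`.
#'
#' @param tau Delay between infection and parasite-induced host death
#'   (time, > 0).
#' @param alpha Transmission rate (1/(parasite x time), > 0).
#' @param beta Progeny released at host death (parasites, > 0). Ignored
#'   when `tradeoff` is supplied.
#' @param delta Free-living parasite decay rate (1/time, > 0).
#' @param tradeoff Optional [tradeoff_function()] linking `beta` to `tau`.
#' @return An object of class `phv_traits`.
#' @export
parasite_traits <- function(tau = 1.5, alpha = 1e-8, beta = 200, delta = 2,
                            tradeoff = NULL) {
  stopifnot(is.numeric(tau), length(tau) == 1, is.finite(tau),
            is.numeric(alpha), length(alpha) == 1, is.finite(alpha),
            is.numeric(delta), length(delta) == 1, is.finite(delta))
  if (tau <= 0) stop("`tau` must be > 0")
  if (alpha <= 0) stop("`alpha` must be > 0")
  if (delta <= 0) stop("`delta` must be > 0")
  if (!is.null(tradeoff)) {
    if (!inherits(tradeoff, "phv_tradeoff"))
      stop("`tradeoff` must be created with tradeoff_function()")
    beta <- beta_of_tau(tradeoff, tau)
  } else {
    stopifnot(is.numeric(beta), length(beta) == 1, is.finite(beta))
    if (beta < 0) stop("`beta` must be >= 0")
  }
  structure(list(tau = tau, alpha = alpha, beta = beta, delta = delta,
                 tradeoff = tradeoff),
            class = "phv_traits")
}

#' Season configuration
#'
#' One phenological environment: season length `T` and the free-parasite
#' density present at the start of the season, `v_init = v1(0)`
#' (the carry-over from the previous season's end-of-season progeny).
#'
#' @param T Season length (time, > 0).
#' @param v_init Start-of-season free parasite density (parasites, >= 0).
#' @return An object of class `phv_season`.
#' @export
season_config <- function(T = 3, v_init = 1) {
  stopifnot(is.numeric(T), length(T) == 1, is.finite(T),
            is.numeric(v_init), length(v_init) == 1, is.finite(v_init))
  if (T <= 0) stop("`T` must be > 0")
  if (v_init < 0) stop("`v_init` must be >= 0")
  structure(list(T = T, v_init = v_init), class = "phv_season")
}

#' Full model parameter set
#'
#' Bundles [host_params()], [parasite_traits()] and [season_config()] into
#' the flat parameter vector used throughout the package. Defaults are the
#' baseline parameterisation of the seasonal obligate-killer model
#' (cohort size 1e8, transmission rate 1e-8, decay rate 2, host death rate
#' 0.5), with season length 3, emergence period 1, incubation delay 1.5 and
#' 200 progeny per killed host.
#'
#' @inheritParams host_params
#' @inheritParams parasite_traits
#' @inheritParams season_config
#' @return An object of class `phv_params`: a named list with elements
#'   `s_hat`, `t_l`, `mu`, `tau`, `alpha`, `beta`, `delta`, `T`, `v_init`
#'   and `tradeoff`.
#' @examples
#' p <- model_params(T = 3.2)
#' season_v2_end(p)
#' @export
model_params <- function(s_hat = 1e8, t_l = 1, mu = 0.5,
                         tau = 1.5, alpha = 1e-8, beta = 200, delta = 2,
                         T = 3, v_init = 1, tradeoff = NULL) {
  host <- host_params(s_hat, t_l, mu)
  traits <- parasite_traits(tau, alpha, beta, delta, tradeoff)
  season <- season_config(T, v_init)
  if (host$t_l > season$T) stop("`t_l` must not exceed the season length `T`")
  structure(c(unclass(host), unclass(traits), unclass(season)),
            class = "phv_params")
}

#' @export
print.phv_params <- function(x, ...) {
  cat("Seasonal obligate-killer model parameters\n")
  cat(sprintf("  host:     s_hat = %.4g, t_l = %.4g, mu = %.4g\n",
              x$s_hat, x$t_l, x$mu))
  cat(sprintf("  parasite: tau = %.4g, alpha = %.4g, beta = %.4g, delta = %.4g\n",
              x$tau, x$alpha, x$beta, x$delta))
  cat(sprintf("  season:   T = %.4g, v_init = %.4g\n", x$T, x$v_init))
  if (!is.null(x$tradeoff))
    cat("  trade-off: ", format(x$tradeoff), "\n", sep = "")
  invisible(x)
}

# Return a modified copy of a phv_params object, revalidated.
#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced and all
#' invariants re-checked. When the parameter set carries a trade-off and
#' `tau` changes, `beta` is re-derived from the trade-off.
#'
#' @param params A [model_params()] object.
#' @param ... Named scalar replacements (e.g. `tau = 2`, `T = 4`).
#' @return A `phv_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "phv_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(params))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p <- unclass(params)
  p[names(repl)] <- repl
  model_params(s_hat = p$s_hat, t_l = p$t_l, mu = p$mu, tau = p$tau,
               alpha = p$alpha, beta = p$beta, delta = p$delta,
               T = p$T, v_init = p$v_init, tradeoff = p$tradeoff)
}

#' Read a parameter configuration file
#'
#' Reads a YAML configuration with a `model` namespace holding the flat
#' parameter names of [model_params()] (`s_hat`, `t_l`, `mu`, `tau`,
#' `alpha`, `beta`, `delta`, `T`, `v_init`), an optional `tradeoff`
#' namespace (`kind`, `a`, `b`) and an optional `ibm` namespace passed to
#' [ibm_config()]. See `system.file("extdata", "default-config.yaml",
#' package = "phenovir")` for a template.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `params` (a `phv_params`) and `ibm`
#'   (an `phv_ibm_config` or `NULL`).
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$model)) stop("config must contain a `model` namespace")
  # YAML 1.1 reads exponents like 1.0e8 as strings; coerce numeric fields
  cfg$model <- lapply(cfg$model, function(v)
    if (is.character(v) && !is.na(suppressWarnings(as.numeric(v))))
      as.numeric(v) else v)
  tr <- NULL
  if (!is.null(cfg$tradeoff) && !identical(cfg$tradeoff$kind, "none")) {
    tr <- tradeoff_function(kind = cfg$tradeoff$kind,
                            a = cfg$tradeoff$a, b = cfg$tradeoff$b)
  }
  params <- do.call(model_params, c(cfg$model, list(tradeoff = tr)))
  ibm <- NULL
  if (!is.null(cfg$ibm)) {
    args <- cfg$ibm
    args$params <- params
    ibm <- do.call(ibm_config, args)
  }
  list(params = params, ibm = ibm)
}
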