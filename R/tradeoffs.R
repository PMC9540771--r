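## Transmission-virulence trade-offs: the progeny number released at host
## death as a function of the incubation delay, beta(tau). Linear forms:
##   linear_positive: beta(tau) = a * (tau + b)   (longer infections, more
##                    progeny)
##   linear_negative: beta(tau) = a * (-tau + b)  (longer infections, fewer
##                    progeny)

#' Transmission-virulence trade-off function
#'
#' Creates a trade-off object mapping the incubation delay `tau` to the
#' progeny number `beta(tau)`. The admissible delay interval is clipped so
#' that `beta(tau) >= beta_min` (default 1 progeny), which excludes
#' pathological zero-progeny boundary optima.
#'
#' @param kind One of `"none"`, `"linear_positive"`, `"linear_negative"`,
#'   `"custom"`.
#' @param a,b Scale and offset of the linear forms (see Details).
#' @param beta Constant progeny number for `kind = "none"`.
#' @param f,f_deriv For `kind = "custom"`: the function `beta(tau)` and
#'   (optionally) its derivative.
#' @param beta_min Smallest admissible progeny number (> 0).
#' @return An object of class `phv_tradeoff` (a function of `tau` with
#'   attributes `kind`, `deriv` and `admissible`).
#' @examples
#' f <- tradeoff_function("linear_positive", a = 99, b = 0.5)
#' beta_of_tau(f, 1.5)
#' @export
tradeoff_function <- function(kind = c("none", "linear_positive",
                                       "linear_negative", "custom"),
                              a = 99, b = 0.5, beta = 200,
                              f = NULL, f_deriv = NULL, beta_min = 1) {
  kind <- match.arg(kind)
  stopifnot(beta_min > 0)
  switch(kind,
    none = {
      stopifnot(beta > 0)
      fun <- function(tau) rep(beta, length(tau))
      dfun <- function(tau) rep(0, length(tau))
      adm <- c(0, Inf)
    },
    linear_positive = {
      stopifnot(a > 0)
      fun <- function(tau) a * (tau + b)
      dfun <- function(tau) rep(a, length(tau))
      adm <- c(max(0, beta_min / a - b), Inf)
    },
    linear_negative = {
      stopifnot(a > 0)
      fun <- function(tau) a * (-tau + b)
      dfun <- function(tau) rep(-a, length(tau))
      adm <- c(0, b - beta_min / a)
      if (adm[2] <= adm[1])
        stop("trade-off admits no positive-progeny delay")
    },
    custom = {
      stopifnot(is.function(f))
      fun <- f
      dfun <- f_deriv %||%
        function(tau) (f(tau + 1e-6) - f(tau - 1e-6)) / 2e-6
      adm <- c(0, Inf)
    })
  structure(fun, kind = kind, deriv = dfun, admissible = adm,
            beta_min = beta_min, class = c("phv_tradeoff", "function"))
}

#' Progeny number under a trade-off
#'
#' Evaluates `beta(tau)`, checking that `tau` lies in the trade-off's
#' admissible interval (where `beta(tau) >= beta_min`).
#'
#' @param f A [tradeoff_function()].
#' @param tau Incubation delay(s).
#' @return Progeny number(s).
#' @export
beta_of_tau <- function(f, tau) {
  stopifnot(inherits(f, "phv_tradeoff"))
  adm <- attr(f, "admissible")
  if (any(tau < adm[1] - 1e-12) || any(tau > adm[2] + 1e-12))
    stop(sprintf(
      "tau outside admissible trade-off interval [%.6g, %.6g]",
      adm[1], adm[2]))
  f(tau)
}

## d log beta / d tau, zero when no trade-off is attached.
.beta_logderiv <- function(f, tau) {
  if (is.null(f)) return(0)
  attr(f, "deriv")(tau) / f(tau)
}

#' @export
format.phv_tradeoff <- function(x, ...) {
  adm <- attr(x, "admissible")
  sprintf("%s trade-off (admissible tau in [%.4g, %.4g])",
          attr(x, "kind"), adm[1], adm[2])
}

#' Compare optimal virulence with and without a trade-off
#'
#' Locates the singular delay `tau_star` for the same phenological
#' environment twice -- once with constant progeny number and once with
#' the progeny number tied to the delay through `tradeoff` -- and reports
#' the direction of the shift. A trade-off rewarding longer infections
#' shifts the optimum towards longer delays (lower virulence); one
#' penalising longer infections shifts it towards shorter delays.
#'
#' @param params A [model_params()] object without a trade-off (its `beta`
#'   is the no-trade-off constant).
#' @param tradeoff A [tradeoff_function()].
#' @param bracket Passed to [find_singular_strategy()].
#' @return A list with `tau_star_with`, `tau_star_without`, `direction`
#'   (sign of the shift) and the two `phv_singular` objects.
#' @export
compare_tradeoff_optima <- function(params, tradeoff, bracket = NULL) {
  stopifnot(inherits(params, "phv_params"),
            inherits(tradeoff, "phv_tradeoff"))
  base <- update_params(params, tradeoff = NULL)
  ss_without <- find_singular_strategy(base, bracket = bracket)
  p_with <- update_params(params, tradeoff = tradeoff)
  br <- bracket %||% (c(0.05, 0.98) * params$T)
  adm <- attr(tradeoff, "admissible")
  br <- c(max(br[1], adm[1] + 1e-6), min(br[2], adm[2] - 1e-6))
  ss_with <- find_singular_strategy(p_with, bracket = br)
  if (!ss_with$found || !ss_without$found)
    stop("no interior singular strategy in one of the two scenarios")
  list(tau_star_with = ss_with$tau_star,
       tau_star_without = ss_without$tau_star,
       direction = sign(ss_with$tau_star - ss_without$tau_star),
       with = ss_with, without = ss_without)
}
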