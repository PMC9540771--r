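## Figure-level experiments: parameter sweeps over season length and
## emergence-period length, and the trade-off comparison, each returning a
## tidy table of optimal strategies.

#' Sweep the season length
#'
#' Locates the singular delay and the resident equilibrium at that delay
#' for each season length in `T_grid` (emergence period and rates held
#' fixed). Cells where the parasite persists nowhere in the search
#' bracket, or where no interior singular strategy exists, are reported as
#' `NA` rather than dropped.
#'
#' @param params A [model_params()] object (its `T` is replaced).
#' @param T_grid Season lengths, each > `params$t_l`.
#' @return A tibble with columns `T`, `tau_star`, `offset`
#'   (`T - tau_star`), `v_star`, `is_ess`, `found`.
#' @export
sweep_season_length <- function(params,
                                T_grid = seq(2.8, 4.0, by = 0.2)) {
  stopifnot(inherits(params, "phv_params"), all(T_grid > params$t_l))
  rows <- lapply(sort(T_grid), function(Ti) {
    ss <- find_singular_strategy(update_params(params, T = Ti))
    tibble::tibble(T = Ti,
                   tau_star = if (ss$found) ss$tau_star else NA_real_,
                   offset = if (ss$found) Ti - ss$tau_star else NA_real_,
                   v_star = if (ss$found) ss$v_star else NA_real_,
                   is_ess = if (ss$found) ss$is_ess else NA,
                   found = ss$found)
  })
  do.call(rbind, rows)
}

#' Sweep the host emergence period
#'
#' As [sweep_season_length()], but varying the length of the emergence
#' period at fixed season length. Captures the non-monotone dependence of
#' the optimal delay on emergence synchrony and the decline of the
#' equilibrium parasite density with increasing emergence variation.
#'
#' @param params A [model_params()] object (its `t_l` is replaced).
#' @param t_l_grid Emergence period lengths, each < `params$T`.
#' @return A tibble with columns `t_l`, `tau_star`, `v_star`, `is_ess`,
#'   `found`.
#' @export
sweep_emergence_period <- function(params,
                                   t_l_grid = c(0.01, 0.25, 0.5, 1.0,
                                                1.5, 2.0, 2.5)) {
  stopifnot(inherits(params, "phv_params"), all(t_l_grid < params$T),
            all(t_l_grid > 0))
  rows <- lapply(sort(t_l_grid), function(tli) {
    ss <- find_singular_strategy(update_params(params, t_l = tli))
    tibble::tibble(t_l = tli,
                   tau_star = if (ss$found) ss$tau_star else NA_real_,
                   v_star = if (ss$found) ss$v_star else NA_real_,
                   is_ess = if (ss$found) ss$is_ess else NA,
                   found = ss$found)
  })
  do.call(rbind, rows)
}

#' Trade-off experiment
#'
#' Compares the optimal delay without a trade-off against the optima
#' under a progeny-rewarding (`linear_positive`) and a progeny-penalising
#' (`linear_negative`) trade-off in the same phenological environment.
#'
#' @param params A [model_params()] object without a trade-off.
#' @param tradeoff_pos,tradeoff_neg The two [tradeoff_function()]s;
#'   defaults are `99 * (tau + 0.5)` and `99 * (-tau + 4)`.
#' @return A tibble with columns `scenario`, `tau_star`, `shift`
#'   (`tau_star - tau_star[no trade-off]`), `v_star`.
#' @export
run_tradeoff_experiment <- function(params,
                                    tradeoff_pos = tradeoff_function(
                                      "linear_positive", a = 99, b = 0.5),
                                    tradeoff_neg = tradeoff_function(
                                      "linear_negative", a = 99, b = 4)) {
  stopifnot(inherits(params, "phv_params"))
  base <- find_singular_strategy(update_params(params, tradeoff = NULL))
  if (!base$found) stop("no interior optimum without trade-off")
  one <- function(tr, name) {
    ss <- find_singular_strategy(update_params(params, tradeoff = tr))
    tibble::tibble(scenario = name,
                   tau_star = if (ss$found) ss$tau_star else NA_real_,
                   shift = if (ss$found) ss$tau_star - base$tau_star
                   else NA_real_,
                   v_star = if (ss$found) ss$v_star else NA_real_)
  }
  rbind(tibble::tibble(scenario = "none", tau_star = base$tau_star,
                       shift = 0, v_star = base$v_star),
        one(tradeoff_pos, "linear_positive"),
        one(tradeoff_neg, "linear_negative"))
}

#' Reproduce all figure-level experiments
#'
#' Runs the season-length sweep, the emergence-period sweep, the
#' trade-off comparison and the individual-based validation; writes each
#' as a tidy CSV into `out_dir` together with a JSON manifest (package
#' version, parameters, seed), and evaluates the headline qualitative
#' claims as named logical checks.
#'
#' @param params Baseline [model_params()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @param seed Seed for the stochastic validator.
#' @param T_grid,t_l_grid Sweep grids.
#' @param n_replicates Individual-based replicates.
#' @return Invisibly, a list with the four result tables and `checks`, a
#'   named logical vector of the qualitative claims.
#' @export
reproduce_all <- function(params = model_params(), out_dir = NULL,
                          seed = 1L,
                          T_grid = seq(2.8, 4.0, by = 0.2),
                          t_l_grid = c(0.01, 0.25, 0.5, 1.0, 1.5, 2.0, 2.5),
                          n_replicates = 50L) {
  swT <- sweep_season_length(update_params(params, t_l = 1), T_grid)
  swL <- sweep_emergence_period(update_params(params, T = 3), t_l_grid)
  tro <- run_tradeoff_experiment(params)
  ibm <- ibm_replicates(ibm_config(params, n_hosts = 1e4, seed = seed,
                                   n_replicates = n_replicates))
  off <- swT$offset[swT$found]
  kmin <- which.min(swL$tau_star)
  checks <- c(
    interior_optimum = all(swT$tau_star > 0 & swT$tau_star < swT$T,
                           na.rm = TRUE),
    tau_star_increases_with_T = !is.unsorted(swT$tau_star[swT$found]),
    fixed_offset_cv_below_10pct =
      stats::sd(off) / mean(off) < 0.10,
    tau_star_nonmonotone_in_t_l =
      kmin > 1 && kmin < nrow(swL) &&
      swL$tau_star[1] > swL$tau_star[kmin] &&
      swL$tau_star[nrow(swL)] > swL$tau_star[kmin],
    equilibrium_decreases_with_t_l = !is.unsorted(rev(swL$v_star)),
    tradeoff_positive_raises_tau =
      tro$shift[tro$scenario == "linear_positive"] > 0,
    tradeoff_negative_lowers_tau =
      tro$shift[tro$scenario == "linear_negative"] < 0,
    ibm_within_3se = abs(ibm$z) < 3)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(swT, file.path(out_dir, "sweep_season_length.csv"),
                     row.names = FALSE)
    utils::write.csv(swL, file.path(out_dir, "sweep_emergence_period.csv"),
                     row.names = FALSE)
    utils::write.csv(tro, file.path(out_dir, "tradeoff_experiment.csv"),
                     row.names = FALSE)
    utils::write.csv(ibm$replicates, file.path(out_dir, "ibm_replicates.csv"),
                     row.names = FALSE)
    manifest <- list(
      package = "phenovir",
      version = as.character(utils::packageVersion("phenovir")),
      seed = seed,
      params = unclass(params)[c("s_hat", "t_l", "mu", "tau", "alpha",
                                 "beta", "delta", "T", "v_init")],
      T_grid = T_grid, t_l_grid = t_l_grid,
      checks = as.list(checks))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(season_length = swT, emergence_period = swL,
                 tradeoff = tro, ibm = ibm, checks = checks))
}
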