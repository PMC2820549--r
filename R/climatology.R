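#' Generate a synthetic monthly climatology
#'
#' Stands in for multi-year satellite climatology means: samples the two
#' seasonal sinusoids at mid-month days `(month - 0.5) * 30` and adds
#' independent Gaussian noise, reproducibly for a given seed. The output is
#' the climatology table consumed by [fit_seasonal_forcing()] and the
#' `fit-forcing` CLI subcommand.
#'
#' @param forcings A [site_forcings()] pair giving the generating sinusoids.
#' @param noise_sd_sst,noise_sd_si Gaussian noise SDs (>= 0) in driver units.
#' @param seed Integer seed.
#' @param path Optional CSV output path (header `month,sst_c,si_kw_m2_d`).
#' @return A tibble with columns `month`, `sst_c`, `si_kw_m2_d` (12 rows).
#' @export
#' @examples
#' generate_synthetic_climatology(noise_sd_sst = 0.2, seed = 7)
generate_synthetic_climatology <- function(forcings = site_forcings("lee_stocking"),
                                           noise_sd_sst = 0, noise_sd_si = 0,
                                           seed = 1L, path = NULL) {
  stopifnot(inherits(forcings$si, "seasonal_forcing"),
            inherits(forcings$sst, "seasonal_forcing"),
            noise_sd_sst >= 0, noise_sd_si >= 0)
  month <- 1:12
  t_mid <- (month - 0.5) * 30
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  out <- tibble::tibble(
    month = month,
    sst_c = eval_forcing(forcings$sst, t_mid) +
      stats::rnorm(12, 0, noise_sd_sst),
    si_kw_m2_d = eval_forcing(forcings$si, t_mid) +
      stats::rnorm(12, 0, noise_sd_si))
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  out
}

#' Read a monthly climatology CSV
#'
#' Expects the dialect written by [generate_synthetic_climatology()]:
#' header `month,sst_c,si_kw_m2_d`, months 1-12, dot decimal, UTF-8.
#'
#' @param path CSV path.
#' @return A tibble with columns `month`, `sst_c`, `si_kw_m2_d`.
#' @export
read_climatology <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("climatology file not found: %s", path), call. = FALSE)
  }
  d <- utils::read.csv(path)
  need <- c("month", "sst_c", "si_kw_m2_d")
  if (!all(need %in% names(d))) {
    stop("climatology CSV must have columns month,sst_c,si_kw_m2_d",
         call. = FALSE)
  }
  tibble::as_tibble(d[need])
}

#' Fit both seasonal drivers from a climatology table
#'
#' @param climatology A tibble from [read_climatology()] /
#'   [generate_synthetic_climatology()].
#' @param period_days Cycle length in days.
#' @return A [site_forcings()] (site `"custom"`) with fitted `si` and `sst`.
#' @export
fit_site_forcings <- function(climatology, period_days = 360) {
  site_forcings(
    "custom",
    si = fit_seasonal_forcing(climatology, "si_kw_m2_d", period_days, "si"),
    sst = fit_seasonal_forcing(climatology, "sst_c", period_days, "sst"))
}

#' Write a trajectory, summary or shuffle report to disk
#'
#' `write_trajectory()` writes the per-day table as CSV plus a JSON sidecar
#' (`<path>.meta.json`) recording the seed, site, scenario and model
#' constants. `write_ensemble_summaries()` writes the tidy per-replicate
#' summary CSV; `write_shuffle_report()` writes the comparison as JSON.
#'
#' @param traj A `symbiont_traj`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "symbiont_traj"))
  utils::write.csv(tibble::as_tibble(traj), path, row.names = FALSE,
                   quote = FALSE)
  p <- attr(traj, "params")
  fo <- attr(traj, "forcings")
  an <- attr(traj, "anomaly")
  meta <- list(
    seed = attr(traj, "seed"),
    site = fo$site %||% "custom",
    scenario = if (is.null(an)) "baseline" else "warming",
    constants = list(c1 = p$c1, c2 = p$c2, c3 = p$c3, k = p$host$k),
    horizon_days = p$horizon_days,
    step_days = p$step_days,
    n_types = nrow(p$traits),
    types = p$traits$label)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @param ensemble An ensemble from [run_scenario()].
#' @export
write_ensemble_summaries <- function(ensemble, path) {
  utils::write.csv(ensemble_summaries(ensemble), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @param report A `shuffle_report` from [compare_scenarios()].
#' @export
write_shuffle_report <- function(report, path) {
  out <- list(detect_threshold = attr(report, "detect_threshold"),
              types = as.list(tibble::as_tibble(report)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Export fitted forcing coefficients as JSON
#'
#' @param forcings A [site_forcings()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_forcing_json <- function(forcings, path) {
  enc <- function(f) list(mean_level = f$mean_level, amplitude = f$amplitude,
                          phase = f$phase, period_days = f$period_days,
                          rss = attr(f, "rss") %||% NULL)
  jsonlite::write_json(list(site = forcings$site %||% "custom",
                            si = enc(forcings$si), sst = enc(forcings$sst)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
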