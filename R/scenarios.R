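#' Seasonal forcing pairs for the two study localities
#'
#' Returns the SI and SST sinusoids for a named site. The shipped
#' coefficients are editable calibration defaults that emulate the two
#' Atlantic localities' multi-year satellite climatologies: Lee Stocking
#' Island (Bahamas) with relatively homogeneous temperatures year-round and
#' persistently high insolation, and Key Largo (Florida) with a much more
#' seasonally variable environment. SST peaks in late August (day 240) and
#' SI in late June (day 172) at both sites.
#'
#' @param site `"lee_stocking"`, `"key_largo"`, or `"custom"` (in which case
#'   `si` and `sst` must be supplied).
#' @param si,sst [seasonal_forcing()] objects for a custom site.
#' @return A list of class `site_forcings` with elements `si`, `sst`, `site`.
#' @export
#' @examples
#' f <- site_forcings("key_largo")
#' eval_forcing(f$sst, c(60, 240))
site_forcings <- function(site = c("lee_stocking", "key_largo", "custom"),
                          si = NULL, sst = NULL) {
  site <- match.arg(site)
  if (site == "custom") {
    if (!inherits(si, "seasonal_forcing") || !inherits(sst, "seasonal_forcing")) {
      stop("custom site needs `si` and `sst` seasonal_forcing objects",
           call. = FALSE)
    }
  } else {
    co <- .site_coefficients[[site]]
    si <- seasonal_forcing(co$si_mean, co$si_amp, phase_for_peak(co$si_peak_day),
                           driver = "si")
    sst <- seasonal_forcing(co$sst_mean, co$sst_amp, phase_for_peak(co$sst_peak_day),
                            driver = "sst")
  }
  structure(list(si = si, sst = sst, site = site), class = "site_forcings")
}

# calibration defaults (see the methods vignette for how they were chosen)
.site_coefficients <- list(
  lee_stocking = list(sst_mean = 27.4, sst_amp = 0.3, sst_peak_day = 240,
                      si_mean = 5.8, si_amp = 0.5, si_peak_day = 172),
  key_largo = list(sst_mean = 26.5, sst_amp = 2.5, sst_peak_day = 240,
                   si_mean = 5.25, si_amp = 1.8, si_peak_day = 172))

#' @export
print.site_forcings <- function(x, ...) {
  cat("<site_forcings>", x$site, "\n")
  print(x$si); print(x$sst)
  invisible(x)
}

#' Scenario specification for an ensemble run
#'
#' @param site Site name passed to [site_forcings()] (or a ready
#'   `site_forcings` object).
#' @param scenario `"baseline"` or `"warming"` (the +1/+1.5/+1 degC
#'   July-September overlay of [warming_schedule()]).
#' @param n_replicates Number of seeded replicate runs (>= 1).
#' @param master_seed Integer seed from which every replicate seed is
#'   derived deterministically.
#' @param anomaly Override the anomaly schedule used when
#'   `scenario = "warming"`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(site = "lee_stocking",
                          scenario = c("baseline", "warming"),
                          n_replicates = 20, master_seed = 1L,
                          anomaly = NULL) {
  scenario <- match.arg(scenario)
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  forcings <- if (inherits(site, "site_forcings")) site else site_forcings(site)
  if (scenario == "warming" && is.null(anomaly)) anomaly <- warming_schedule()
  if (scenario == "baseline") anomaly <- NULL
  structure(list(forcings = forcings, scenario = scenario,
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed), anomaly = anomaly),
            class = "scenario_spec")
}

# replicate seeds derived from the master seed, all < 2^31
replicate_seeds <- function(master_seed, n) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(master_seed %% 2147483647))
  sample.int(2147483646L, n)
}

#' Run a seeded ensemble of simulations for one scenario
#'
#' Runs `n_replicates` simulations whose seeds are derived deterministically
#' from the master seed, so the whole ensemble is bit-reproducible.
#'
#' @param spec A [scenario_spec()].
#' @param params A [model_params()].
#' @return A tibble with one row per replicate and columns `replicate`,
#'   `seed`, `trajectory` (list of `symbiont_traj`) and `summary` (list of
#'   per-type summary tibbles from [summarize_trajectory()]). Unnest the
#'   summaries with [ensemble_summaries()].
#' @export
#' @examples
#' ens <- run_scenario(scenario_spec(n_replicates = 2), model_params(horizon_days = 720))
#' ensemble_summaries(ens)
run_scenario <- function(spec, params = model_params()) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(params, "model_params"))
  seeds <- replicate_seeds(spec$master_seed, spec$n_replicates)
  trajs <- lapply(seeds, function(s) {
    simulate_symbionts(params, spec$forcings, spec$anomaly, seed = s)
  })
  summaries <- lapply(trajs, summarize_trajectory)
  tibble::tibble(replicate = seq_along(seeds), seed = seeds,
                 trajectory = trajs, summary = summaries)
}

#' Per-replicate, per-type summaries of an ensemble
#'
#' @param ensemble The tibble returned by [run_scenario()].
#' @return A tibble with columns `replicate`, `type`, `final_year_mean`,
#'   `rel_abund`, `rank`, `min_density`.
#' @export
ensemble_summaries <- function(ensemble) {
  stopifnot(is.data.frame(ensemble), "summary" %in% names(ensemble))
  tidyr::unnest(dplyr::select(ensemble, "replicate", "summary"),
                cols = "summary")
}

#' Summarise a simulated trajectory
#'
#' Final-year (last 360 days) mean density per type, the corresponding
#' relative abundances, a dominance rank (1 = most abundant in the final
#' year; ties broken by trait-table order), and each type's minimum density
#' over the whole run. Annual peak months of the total density are attached
#' as attribute `"annual_peak_months"` (also available via
#' [annual_peak_months()]).
#'
#' @param traj A `symbiont_traj` from [simulate_symbionts()].
#' @return A tibble with one row per type: `type`, `final_year_mean`,
#'   `rel_abund`, `rank`, `min_density`.
#' @export
summarize_trajectory <- function(traj) {
  stopifnot(inherits(traj, "symbiont_traj"))
  labels <- attr(traj, "params")$traits$label
  zm <- as.matrix(tibble::as_tibble(traj)[paste0("z_", labels)])
  horizon <- max(traj$day)
  final <- traj$day > horizon - 360 & traj$day <= horizon
  if (!any(final)) final <- rep(TRUE, nrow(zm))  # short runs: use everything
  fm <- colMeans(zm[final, , drop = FALSE])
  tot <- sum(fm)
  rel <- if (tot > 0) fm / tot else rep(NA_real_, length(fm))
  out <- tibble::tibble(
    type = labels,
    final_year_mean = unname(fm),
    rel_abund = unname(rel),
    rank = unname(rank(-fm, ties.method = "first")),
    min_density = unname(apply(zm, 2, min)))
  attr(out, "annual_peak_months") <- annual_peak_months(traj)
  out
}

#' Month of each simulated year's total-density maximum
#'
#' @param traj A `symbiont_traj`.
#' @return A tibble with columns `year` and `peak_month` (1-12). Within a
#'   year, ties go to the earliest day.
#' @export
annual_peak_months <- function(traj) {
  stopifnot(inherits(traj, "symbiont_traj"))
  labels <- attr(traj, "params")$traits$label
  d <- tibble::as_tibble(traj)
  d <- d[d$day >= 1, , drop = FALSE]
  if (nrow(d) == 0) {
    return(tibble::tibble(year = integer(0), peak_month = integer(0)))
  }
  total <- rowSums(as.matrix(d[paste0("z_", labels)]))
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(day = d$day, total = total,
                                   year = year_of_day(d$day)),
                    .data$year),
    peak_month = month_of_day(.data$day[which.max(.data$total)]),
    .groups = "drop")
}

#' Compare baseline and warmed ensembles: the shuffling report
#'
#' Quantifies endogenous symbiont shuffling between two ensembles of equal
#' size: the per-type change in ensemble-median relative abundance and
#' dominance rank, and an "emergence" flag set when a type's median relative
#' abundance rises from below to at or above the detectability threshold
#' (~5% is the level field methods of the mid-2000s could resolve).
#'
#' @param baseline,warmed Ensemble tibbles from [run_scenario()] (or their
#'   [ensemble_summaries()] tables) with identical type sets and replicate
#'   counts.
#' @param detect_threshold Relative-abundance detectability threshold
#'   (fraction; default 0.05).
#' @return A `shuffle_report` tibble with one row per type: median relative
#'   abundances and ranks in both arms, their changes (`delta_rel_abund`,
#'   `delta_rank`; positive `delta_rank` means the type moved up), and
#'   flags `detectable_baseline`, `detectable_warmed`, `emerged`.
#' @export
compare_scenarios <- function(baseline, warmed, detect_threshold = 0.05) {
  bs <- if ("summary" %in% names(baseline)) ensemble_summaries(baseline) else baseline
  ws <- if ("summary" %in% names(warmed)) ensemble_summaries(warmed) else warmed
  stopifnot(detect_threshold >= 0, detect_threshold <= 1)
  if (!setequal(unique(bs$type), unique(ws$type))) {
    stop("baseline and warmed ensembles have different type sets", call. = FALSE)
  }
  if (dplyr::n_distinct(bs$replicate) != dplyr::n_distinct(ws$replicate)) {
    stop("baseline and warmed ensembles have different replicate counts",
         call. = FALSE)
  }
  med <- function(s, arm) {
    out <- dplyr::summarise(dplyr::group_by(s, .data$type),
                            rel_abund = stats::median(.data$rel_abund),
                            rank = stats::median(.data$rank),
                            .groups = "drop")
    names(out)[2:3] <- paste0(c("rel_abund_", "rank_"), arm)
    out
  }
  out <- dplyr::left_join(med(bs, "baseline"), med(ws, "warmed"), by = "type")
  out <- dplyr::mutate(
    out,
    delta_rel_abund = .data$rel_abund_warmed - .data$rel_abund_baseline,
    delta_rank = .data$rank_baseline - .data$rank_warmed,
    detectable_baseline = .data$rel_abund_baseline >= detect_threshold,
    detectable_warmed = .data$rel_abund_warmed >= detect_threshold,
    emerged = !.data$detectable_baseline & .data$detectable_warmed)
  structure(out, class = c("shuffle_report", class(out)),
            detect_threshold = detect_threshold)
}

#' @export
print.shuffle_report <- function(x, ...) {
  cat(sprintf("<shuffle_report> detectability threshold %.3g\n",
              attr(x, "detect_threshold")))
  NextMethod()
}
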