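#' Default run configuration
#'
#' The full standard parameterization as a plain list: four-type trait
#' table, host envelope (optima 5.5/27, SDs 2.0/3.0, K = 5e6), constants
#' C1 = 0.01 and the calibrated C2 = 8, C3 = 1, the 360-day calendar with a
#' 3600-day (10-year) horizon, the Lee Stocking Island site, a baseline
#' scenario, 20 replicates and seed 1.
#'
#' @return A named list (a valid run configuration).
#' @seealso [load_config()]
#' @export
default_config <- function() {
  tr <- default_traits()
  list(
    constants = list(c1 = 0.01, c2 = 8, c3 = 1, k = 5e6),
    horizon_days = 3600,
    step_days = 1,
    site = "lee_stocking",
    forcing = NULL,
    host = list(si_opt = 5.5, sst_opt = 27, si_width = 2.0, sst_width = 3.0),
    traits = lapply(seq_len(nrow(tr)), function(i) {
      list(label = tr$label[i], si_opt = tr$si_opt[i], sst_opt = tr$sst_opt[i],
           si_sd = tr$si_sd[i], sst_sd = tr$sst_sd[i],
           r_i = tr$r_i[i], z0 = tr$z0[i])
    }),
    scenario = list(warming = FALSE,
                    anomaly = list(months = c(7L, 8L, 9L),
                                   deltas = c(1, 1.5, 1)),
                    mode = "every_year", prob = 1),
    n_replicates = 20L,
    seed = 1L)
}

.config_keys <- list(
  top = c("constants", "horizon_days", "step_days", "site", "forcing",
          "host", "traits", "scenario", "n_replicates", "seed"),
  constants = c("c1", "c2", "c3", "k"),
  host = c("si_opt", "sst_opt", "si_width", "sst_width"),
  trait = c("label", "si_opt", "sst_opt", "si_sd", "sst_sd", "r_i", "z0",
            "si_draw_sd", "sst_draw_sd"),
  scenario = c("warming", "anomaly", "mode", "prob"),
  anomaly = c("months", "deltas"),
  forcing = c("si", "sst"),
  forcing_driver = c("mean_level", "amplitude", "phase", "period_days"))

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop(sprintf("unknown configuration key(s) under %s: %s",
                 where, paste(bad, collapse = ", ")), call. = FALSE)
  }
}

#' Load and validate a run configuration from YAML
#'
#' Reads a YAML configuration, rejects unknown keys, fills every missing
#' value from [default_config()] (logging applied defaults and overrides
#' when `verbose`), and validates the result: positive constants, positive
#' niche widths, known site, a well-formed anomaly schedule. An empty file
#' yields the full default (standard) parameterization.
#'
#' @param path Path to a YAML file.
#' @param verbose Report applied defaults and overrides via [message()].
#' @return A validated configuration list of class `run_config`.
#' @export
load_config <- function(path, verbose = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("config must be a YAML mapping", call. = FALSE)
  as_run_config(user, verbose = verbose)
}

#' @rdname load_config
#' @param config A configuration list (possibly partial).
#' @export
as_run_config <- function(config = list(), verbose = FALSE) {
  def <- default_config()
  check_keys(config, .config_keys$top, "the top level")
  note <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))

  cfg <- def
  for (key in names(config)) cfg[[key]] <- config[[key]]
  for (key in setdiff(.config_keys$top, names(config))) {
    if (key != "forcing") note("config: using default `%s`", key)
  }

  # constants
  check_keys(config$constants, .config_keys$constants, "`constants`")
  cfg$constants <- utils::modifyList(def$constants, config$constants %||% list())
  for (nm in .config_keys$constants) {
    v <- cfg$constants[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("constants.%s must be a positive number", nm), call. = FALSE)
    }
    if (!is.null(config$constants[[nm]])) {
      note("config: override constants.%s = %g", nm, v)
    }
  }

  # host
  check_keys(config$host, .config_keys$host, "`host`")
  cfg$host <- utils::modifyList(def$host, config$host %||% list())
  if (cfg$host$si_width <= 0) stop("host.si_width must be > 0", call. = FALSE)
  if (cfg$host$sst_width <= 0) stop("host.sst_width must be > 0", call. = FALSE)

  # traits
  if (!is.null(config$traits)) {
    if (!is.list(config$traits) || length(config$traits) < 1L) {
      stop("`traits` must be a non-empty list of type entries", call. = FALSE)
    }
    for (i in seq_along(config$traits)) {
      check_keys(config$traits[[i]], .config_keys$trait,
                 sprintf("`traits[%d]`", i))
      tri <- config$traits[[i]]
      for (nm in c("label", "si_opt", "sst_opt", "si_sd", "sst_sd")) {
        if (is.null(tri[[nm]])) {
          stop(sprintf("traits[%d].%s is required", i, nm), call. = FALSE)
        }
      }
      if (tri$si_sd <= 0) {
        stop(sprintf("traits[%d].si_sd must be > 0", i), call. = FALSE)
      }
      if (tri$sst_sd <= 0) {
        stop(sprintf("traits[%d].sst_sd must be > 0", i), call. = FALSE)
      }
      if (!is.null(tri$r_i) && tri$r_i <= 0) {
        stop(sprintf("traits[%d].r_i must be > 0", i), call. = FALSE)
      }
      if (!is.null(tri$z0) && tri$z0 < 0) {
        stop(sprintf("traits[%d].z0 must be >= 0", i), call. = FALSE)
      }
      tri <- utils::modifyList(list(r_i = 1, z0 = 1e6), tri)
      config$traits[[i]] <- tri[intersect(.config_keys$trait, names(tri))]
    }
    cfg$traits <- config$traits
  }

  # site / forcing
  if (!cfg$site %in% c("lee_stocking", "key_largo", "custom")) {
    stop(sprintf("unknown site: %s", cfg$site), call. = FALSE)
  }
  if (cfg$site == "custom") {
    check_keys(cfg$forcing, .config_keys$forcing, "`forcing`")
    for (drv in c("si", "sst")) {
      fd <- cfg$forcing[[drv]]
      if (is.null(fd)) {
        stop(sprintf("site `custom` requires forcing.%s", drv), call. = FALSE)
      }
      check_keys(fd, .config_keys$forcing_driver, sprintf("`forcing.%s`", drv))
      if (is.null(fd$mean_level) || is.null(fd$amplitude)) {
        stop(sprintf("forcing.%s needs mean_level and amplitude", drv),
             call. = FALSE)
      }
    }
  } else if (!is.null(config$forcing)) {
    stop("`forcing` may only be given with site `custom`", call. = FALSE)
  }

  # scenario
  check_keys(config$scenario, .config_keys$scenario, "`scenario`")
  cfg$scenario <- utils::modifyList(def$scenario, config$scenario %||% list())
  check_keys(cfg$scenario$anomaly, .config_keys$anomaly, "`scenario.anomaly`")
  if (!cfg$scenario$mode %in% c("every_year", "random_years")) {
    stop("scenario.mode must be every_year or random_years", call. = FALSE)
  }
  # constructing the schedule validates months/deltas/prob
  anomaly_schedule(cfg$scenario$anomaly$months, cfg$scenario$anomaly$deltas,
                   cfg$scenario$mode, cfg$scenario$prob)

  if (cfg$n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (cfg$horizon_days < 0) stop("horizon_days must be >= 0", call. = FALSE)
  if (cfg$step_days <= 0) stop("step_days must be > 0", call. = FALSE)
  cfg$horizon_days <- as.numeric(cfg$horizon_days)
  cfg$n_replicates <- as.integer(cfg$n_replicates)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("run_config", "list"))
}

#' Write a configuration back to YAML
#'
#' A configuration survives a load -> save -> load round trip unchanged.
#'
#' @param config A `run_config` (or plain list).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Build model objects from a configuration
#'
#' @param config A `run_config` from [load_config()] / [as_run_config()].
#' @return `config_params()`: a [model_params()]; `config_forcings()`: a
#'   [site_forcings()]; `config_anomaly()`: an [anomaly_schedule()] or
#'   `NULL` for a baseline configuration.
#' @export
config_params <- function(config) {
  tr <- dplyr::bind_rows(lapply(config$traits, tibble::as_tibble))
  host <- host_envelope(config$host$si_opt, config$host$sst_opt,
                        config$host$si_width, config$host$sst_width,
                        config$constants$k)
  model_params(traits = tr, host = host,
               c1 = config$constants$c1, c2 = config$constants$c2,
               c3 = config$constants$c3,
               step_days = config$step_days,
               horizon_days = config$horizon_days)
}

#' @rdname config_params
#' @export
config_forcings <- function(config) {
  if (config$site != "custom") return(site_forcings(config$site))
  mk <- function(fd, driver) {
    seasonal_forcing(fd$mean_level, fd$amplitude, fd$phase %||% 0,
                     fd$period_days %||% 360, driver)
  }
  site_forcings("custom",
                si = mk(config$forcing$si, "si"),
                sst = mk(config$forcing$sst, "sst"))
}

#' @rdname config_params
#' @export
config_anomaly <- function(config) {
  if (!isTRUE(config$scenario$warming)) return(NULL)
  anomaly_schedule(config$scenario$anomaly$months,
                   config$scenario$anomaly$deltas,
                   config$scenario$mode, config$scenario$prob)
}
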