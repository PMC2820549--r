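#' Seasonal sinusoidal forcing
#'
#' A single environmental driver (solar insolation, SI, in kW m^-2 d^-1, or
#' sea-surface temperature, SST, in degrees C) modelled as
#' `value(t) = mean_level + amplitude * sin(angular_frequency * t + phase)`,
#' the locality-specific annual curve fitted from multi-year satellite
#' climatology means. The model year is 360 days (twelve 30-day months), so
#' the default angular frequency is `2 * pi / 360` per day.
#'
#' @param mean_level Annual mean of the driver (driver units).
#' @param amplitude Half peak-to-trough seasonal range (driver units, >= 0).
#' @param phase Phase shift in radians. See [phase_for_peak()] to place the
#'   seasonal maximum on a calendar day.
#' @param period_days Length of the seasonal cycle in days (default 360).
#' @param driver Optional label, `"si"` or `"sst"`, carried for printing and
#'   plotting only.
#'
#' @return An object of class `seasonal_forcing`.
#' @seealso [eval_forcing()], [fit_seasonal_forcing()], [site_forcings()]
#' @export
#' @examples
#' f <- seasonal_forcing(27, 2.5, phase_for_peak(240))
#' eval_forcing(f, c(60, 240))
seasonal_forcing <- function(mean_level, amplitude, phase = 0,
                             period_days = 360, driver = NULL) {
  stopifnot(is.numeric(mean_level), length(mean_level) == 1L, is.finite(mean_level),
            is.numeric(amplitude), length(amplitude) == 1L, is.finite(amplitude),
            is.numeric(phase), length(phase) == 1L, is.finite(phase))
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  if (period_days <= 0) stop("`period_days` must be > 0", call. = FALSE)
  structure(
    list(mean_level = mean_level,
         amplitude = amplitude,
         angular_frequency = 2 * pi / period_days,
         phase = phase,
         period_days = period_days,
         driver = driver),
    class = "seasonal_forcing")
}

#' @export
print.seasonal_forcing <- function(x, ...) {
  lab <- if (is.null(x$driver)) "driver" else toupper(x$driver)
  cat(sprintf(
    "<seasonal_forcing %s> %.4g + %.4g * sin(2*pi*t/%g + %.4g)\n",
    lab, x$mean_level, x$amplitude, x$period_days, x$phase))
  invisible(x)
}

#' Phase placing the seasonal maximum on a given day
#'
#' Returns the phase (radians) for which a [seasonal_forcing()] sinusoid
#' peaks at day `peak_day` of the 360-day model year.
#'
#' @param peak_day Day of year (1-360) of the seasonal maximum.
#' @param period_days Cycle length in days.
#' @return Phase in radians.
#' @export
phase_for_peak <- function(peak_day, period_days = 360) {
  pi / 2 - 2 * pi * peak_day / period_days
}

#' Evaluate a seasonal driver at given days
#'
#' @param f A [seasonal_forcing()] object.
#' @param t Numeric vector of days (t >= 0).
#' @return Driver values at `t` (same units as the forcing).
#' @export
eval_forcing <- function(f, t) {
  stopifnot(inherits(f, "seasonal_forcing"), is.numeric(t), all(t >= 0))
  f$mean_level + f$amplitude * sin(f$angular_frequency * t + f$phase)
}

# --- model calendar: twelve 30-day months, 360-day year ---------------------

#' Model calendar helpers
#'
#' The simulator uses an idealised calendar of twelve 30-day months
#' (January = days 1-30, ..., December = days 331-360) and a 360-day year.
#' `month_of_day()` and `year_of_day()` map a simulation day to that
#' calendar; day 0 (the initial state) is assigned to January of year 1.
#'
#' @param t Numeric vector of simulation days (>= 0).
#' @return Integer vector of month indices 1-12, or year indices (1-based).
#' @export
month_of_day <- function(t) {
  stopifnot(all(t >= 0))
  as.integer(((ceiling(pmax(t, 1) / 30) - 1) %% 12) + 1)
}

#' @rdname month_of_day
#' @export
year_of_day <- function(t) {
  stopifnot(all(t >= 0))
  as.integer(ceiling(pmax(t, 1) / 360))
}

# --- thermal anomaly overlay ------------------------------------------------

#' Monthly thermal-anomaly schedule
#'
#' A bleaching-stress scenario adds fixed temperature offsets to the baseline
#' SST curve over whole calendar months. The default schedule is the
#' above-average summer experiment: +1 degC in July, +1.5 degC in August and
#' +1 degC in September. In `"every_year"` mode the overlay repeats every
#' simulated year; in `"random_years"` mode each year is independently
#' subjected to the overlay with probability `prob` (seeded via
#' [select_anomaly_years()]).
#'
#' @param months Integer vector of month indices (1-12).
#' @param deltas Numeric vector of offsets (degrees C), one per month.
#' @param mode `"every_year"` or `"random_years"`.
#' @param prob Per-year probability of applying the overlay in
#'   `"random_years"` mode.
#' @return An object of class `anomaly_schedule`.
#' @export
anomaly_schedule <- function(months, deltas,
                             mode = c("every_year", "random_years"),
                             prob = 1) {
  mode <- match.arg(mode)
  stopifnot(length(months) == length(deltas), length(months) >= 1L)
  months <- as.integer(months)
  if (any(months < 1L | months > 12L)) {
    stop("anomaly `months` must be in 1..12", call. = FALSE)
  }
  if (anyDuplicated(months)) stop("anomaly `months` must be unique", call. = FALSE)
  if (!all(is.finite(deltas))) stop("anomaly `deltas` must be finite", call. = FALSE)
  if (prob < 0 || prob > 1) stop("`prob` must be in [0, 1]", call. = FALSE)
  structure(list(months = months, deltas = as.numeric(deltas),
                 mode = mode, prob = prob),
            class = "anomaly_schedule")
}

#' @rdname anomaly_schedule
#' @export
warming_schedule <- function(mode = c("every_year", "random_years"), prob = 1) {
  anomaly_schedule(months = 7:9, deltas = c(1, 1.5, 1), mode = mode, prob = prob)
}

#' @export
print.anomaly_schedule <- function(x, ...) {
  cat("<anomaly_schedule>", x$mode,
      if (x$mode == "random_years") sprintf("(p = %g)", x$prob) else "", "\n")
  cat(paste(sprintf("  month %2d: %+g degC", x$months, x$deltas),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Choose which simulated years receive the anomaly overlay
#'
#' In `"every_year"` mode all years are selected. In `"random_years"` mode
#' each year is selected independently with probability `prob`, reproducibly
#' for a given seed.
#'
#' @param sched An [anomaly_schedule()].
#' @param n_years Number of simulated years.
#' @param seed Integer seed for the random-year draw.
#' @return Logical vector of length `n_years`.
#' @export
select_anomaly_years <- function(sched, n_years, seed = 1L) {
  stopifnot(inherits(sched, "anomaly_schedule"), n_years >= 0)
  if (n_years == 0) return(logical(0))
  if (sched$mode == "every_year") return(rep(TRUE, n_years))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed %% 2147483647L)
  stats::runif(n_years) < sched$prob
}

#' Thermal-anomaly offset at given days
#'
#' @param sched An [anomaly_schedule()] or `NULL` (no anomaly, offset 0).
#' @param t Numeric vector of days.
#' @param years_active Logical vector (one entry per simulated year) saying
#'   which years receive the overlay; defaults to all years.
#' @return Numeric vector of SST offsets (degrees C) at each `t`.
#' @export
anomaly_delta <- function(sched, t, years_active = NULL) {
  if (is.null(sched)) return(rep(0, length(t)))
  stopifnot(inherits(sched, "anomaly_schedule"))
  m <- month_of_day(t)
  idx <- match(m, sched$months)
  delta <- ifelse(is.na(idx), 0, sched$deltas[idx])
  if (!is.null(years_active)) {
    yr <- year_of_day(t)
    stopifnot(max(yr) <= length(years_active))
    delta <- delta * as.numeric(years_active[yr])
  }
  delta
}

#' Evaluate SST with an anomaly overlay
#'
#' Baseline seasonal SST plus the scheduled monthly offset (0 outside
#' scheduled months or in unselected years).
#'
#' @inheritParams eval_forcing
#' @inheritParams anomaly_delta
#' @return SST values (degrees C) at `t`.
#' @export
eval_sst <- function(f, t, sched = NULL, years_active = NULL) {
  eval_forcing(f, t) + anomaly_delta(sched, t, years_active)
}

# --- fitting a sinusoid to a monthly climatology ----------------------------

#' Fit a seasonal sinusoid to a monthly climatology
#'
#' Least-squares fit of `a + b*sin(w*t + phi)` at the fixed annual frequency
#' `w = 2*pi/period_days`, linearised as mean + in-phase + quadrature terms
#' (`a + p*sin(w*t) + q*cos(w*t)`) and refit via [stats::lm()]. Monthly
#' values are located at mid-month days `(month - 0.5) * 30`, matching
#' [generate_synthetic_climatology()], so a noiseless round trip recovers
#' the generating coefficients exactly.
#'
#' @param climatology A data frame with a `month` column (1-12) and the
#'   driver values in `value_col`.
#' @param value_col Name of the column holding the driver values.
#' @param period_days Cycle length in days (default 360).
#' @param driver Optional driver label stored on the result.
#' @return A [seasonal_forcing()] object with attributes `rss` (residual sum
#'   of squares), `n` (points used) and `sigma` (residual standard error);
#'   retrieve them with [glance()].
#' @export
#' @examples
#' clim <- generate_synthetic_climatology(seed = 1)
#' fit_seasonal_forcing(clim, "sst_c", driver = "sst")
fit_seasonal_forcing <- function(climatology, value_col,
                                 period_days = 360, driver = NULL) {
  stopifnot(is.data.frame(climatology), "month" %in% names(climatology),
            value_col %in% names(climatology))
  month <- climatology$month
  y <- climatology[[value_col]]
  keep <- is.finite(y)
  month <- month[keep]; y <- y[keep]
  if (length(y) < 4L) {
    stop("need at least 4 finite monthly points to fit a seasonal curve",
         call. = FALSE)
  }
  if (any(month < 1 | month > 12)) stop("`month` must be in 1..12", call. = FALSE)
  tm <- (month - 0.5) * 30
  w <- 2 * pi / period_days
  if (stats::sd(y) == 0) {
    warning("constant climatology: amplitude set to 0", call. = FALSE)
    out <- seasonal_forcing(mean(y), 0, 0, period_days, driver)
    attr(out, "rss") <- 0; attr(out, "n") <- length(y); attr(out, "sigma") <- 0
    return(out)
  }
  fit <- stats::lm(y ~ sin(w * tm) + cos(w * tm))
  cf <- stats::coef(fit)
  p <- unname(cf[2]); q <- unname(cf[3])
  amplitude <- sqrt(p^2 + q^2)
  phase <- atan2(q, p)  # p*sin + q*cos = A*sin(wt + phi)
  out <- seasonal_forcing(unname(cf[1]), amplitude, phase, period_days, driver)
  attr(out, "rss") <- sum(stats::residuals(fit)^2)
  attr(out, "n") <- length(y)
  attr(out, "sigma") <- stats::sigma(fit)
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a seasonal forcing into a coefficient table
#'
#' @param x A [seasonal_forcing()].
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.seasonal_forcing <- function(x, ...) {
  tibble::tibble(
    term = c("mean_level", "amplitude", "phase", "angular_frequency",
             "period_days"),
    estimate = c(x$mean_level, x$amplitude, x$phase, x$angular_frequency,
                 x$period_days))
}

#' One-row fit summary of a seasonal forcing
#'
#' @param x A [seasonal_forcing()], typically from [fit_seasonal_forcing()].
#' @param ... Unused.
#' @return A one-row tibble with `rss`, `sigma` and `n` (NA for forcings not
#'   produced by a fit).
#' @export
glance.seasonal_forcing <- function(x, ...) {
  tibble::tibble(
    rss = attr(x, "rss", exact = TRUE) %||% NA_real_,
    sigma = attr(x, "sigma", exact = TRUE) %||% NA_real_,
    n = attr(x, "n", exact = TRUE) %||% NA_integer_)
}

# keep/restore the global RNG state around internal seeded draws
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
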