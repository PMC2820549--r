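#' Model parameters for the symbiont-competition simulator
#'
#' Bundles the dimensionless rate constants, trait table, host envelope and
#' run geometry. C1 scales the conversion of insolation into proliferation
#' resource (standard value 0.01); C2 scales the specific growth rate and
#' C3 the specific loss rate. The standard parameterization leaves C2 and
#' C3 free; the defaults (C2 = 8, C3 = 1) are the calibrated values under
#' which the default sites reproduce the expected ten-year pattern (see
#' the methods vignette). The default horizon is 10 model years = 3600
#' days of the 360-day calendar, advanced in 1-day steps.
#'
#' @param traits Trait table (see [default_traits()]).
#' @param host A [host_envelope()].
#' @param c1,c2,c3 Positive rate constants.
#' @param step_days Iteration step length in days.
#' @param horizon_days Run length in days (multiple of `step_days`).
#' @return An object of class `model_params`.
#' @export
model_params <- function(traits = default_traits(), host = host_envelope(),
                         c1 = 0.01, c2 = 8, c3 = 1,
                         step_days = 1, horizon_days = 3600) {
  traits <- validate_traits(traits)
  stopifnot(inherits(host, "host_envelope"))
  for (nm in c("c1", "c2", "c3")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive number", nm), call. = FALSE)
    }
  }
  if (step_days <= 0) stop("`step_days` must be > 0", call. = FALSE)
  if (horizon_days < 0 || horizon_days %% step_days != 0) {
    stop("`horizon_days` must be a non-negative multiple of `step_days`",
         call. = FALSE)
  }
  structure(list(traits = traits, host = host, c1 = c1, c2 = c2, c3 = c3,
                 step_days = step_days, horizon_days = horizon_days),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> %d symbiont types, C1 = %g, C2 = %g, C3 = %g, %g days in %g-day steps\n",
    nrow(x$traits), x$c1, x$c2, x$c3, x$horizon_days, x$step_days))
  invisible(x)
}

#' Resource available for symbiont proliferation
#'
#' Down-welling insolation converted into proliferation resource, shaded
#' down linearly as the standing symbiont population approaches the host
#' maximum K (self-shading makes light limiting at high density):
#' `r_pro = C1 * SI * max(0, 1 - total_z / K)`.
#'
#' @param si Solar insolation (kW m^-2 d^-1, >= 0). Vectorised.
#' @param total_z Total symbiont density, sum of all types (cells cm^-2).
#' @param params A [model_params()].
#' @return `r_pro` (kW m^-2 d^-1), non-negative, decreasing in `total_z`.
#' @export
resource_allocation <- function(si, total_z, params) {
  stopifnot(inherits(params, "model_params"),
            all(si >= 0), all(total_z >= 0))
  params$c1 * si * pmax(0, 1 - total_z / params$host$k)
}

#' Specific growth rate of each symbiont type
#'
#' Gaussian niche response around the (possibly per-step drawn) optima,
#' scaled by the shared proliferation resource and the type's resource
#' requirement:
#' `mu_i = C2 * (r_pro / R_i) * exp(-(si - si_opt)^2 / (2*alpha^2)) *
#' exp(-(sst - sst_opt)^2 / (2*beta^2))`.
#' The rate is maximal exactly at the drawn optima (peak `C2 * r_pro / R_i`)
#' and strictly positive whenever `r_pro > 0`.
#'
#' @param si,sst Scalar environmental conditions at this step.
#' @param r_pro Resource allocated to proliferation (from
#'   [resource_allocation()]).
#' @param traits Trait table; `si_sd`/`sst_sd` are the Gaussian widths
#'   (alpha_i, beta_i) and must be positive.
#' @param c2 Growth constant C2.
#' @param si_opt,sst_opt Realised optima for this step (default: the trait
#'   means; pass a row of [sample_optima()] draws for a stochastic step).
#' @return Numeric vector `mu_i`, one entry per type (dimensionless).
#' @export
growth_rate <- function(si, sst, r_pro, traits, c2 = 1,
                        si_opt = traits$si_opt, sst_opt = traits$sst_opt) {
  traits <- validate_traits(traits)
  stopifnot(length(si) == 1L, length(sst) == 1L, length(r_pro) == 1L,
            r_pro >= 0)
  c2 * (r_pro / traits$r_i) *
    exp(-(si - si_opt)^2 / (2 * traits$si_sd^2)) *
    exp(-(sst - sst_opt)^2 / (2 * traits$sst_sd^2))
}

#' Environmentally dependent sustainable density Kc
#'
#' The density of symbionts the host can sustain under the current
#' conditions: the maximum carrying capacity K weighted by Gaussian host
#' tolerance in both drivers,
#' `Kc = K * exp(-(si - hSI_opt)^2 / (2*gamma^2)) *
#' exp(-(sst - hSST_opt)^2 / (2*h_sst_sd^2))`.
#' `0 < Kc <= K`, with equality iff both drivers sit at the host optima.
#'
#' @param si,sst Environmental conditions (vectorised).
#' @param host A [host_envelope()].
#' @return `Kc` in cells cm^-2.
#' @export
env_carrying_capacity <- function(si, sst, host) {
  stopifnot(inherits(host, "host_envelope"))
  host$k *
    exp(-(si - host$si_opt)^2 / (2 * host$si_width^2)) *
    exp(-(sst - host$sst_opt)^2 / (2 * host$sst_width^2))
}

#' Specific loss rate of symbionts from the host
#'
#' Excess symbionts relative to the sustainable density Kc are expelled
#' randomly and independently of type:
#' `mu_loss = min(1, C3 * max(0, total_z - kc) / total_z)` (0 when
#' `total_z = 0`). The same scalar applies to every type, and the cap at 1
#' means no more than the standing stock can be lost in one step.
#'
#' @param total_z Total symbiont density (cells cm^-2, >= 0). Vectorised.
#' @param kc Sustainable density Kc (cells cm^-2, > 0).
#' @param c3 Loss constant C3 (> 0).
#' @return `mu_loss` in `[0, 1]`.
#' @export
loss_rate <- function(total_z, kc, c3 = 1) {
  if (any(!is.finite(kc)) || any(kc <= 0)) {
    stop("`kc` must be > 0", call. = FALSE)
  }
  stopifnot(all(total_z >= 0), c3 > 0)
  ifelse(total_z == 0, 0,
         pmin(1, c3 * pmax(0, total_z - kc) / total_z))
}

#' Advance the symbiont populations by one iteration step
#'
#' One application of the population balance
#' `Z_i(t+1) = Z_i(t) + mu_i(t) * Z_i(t) - mu_loss(t) * Z_i(t)`, with the
#' step's shared resource `r_pro`, sustainable density `Kc` and loss
#' `mu_loss`, and per-type growth from this step's drawn optima.
#'
#' @param z Numeric vector of current densities, one per type (>= 0).
#' @param si,sst Environmental conditions at this step.
#' @param params A [model_params()].
#' @param si_opt,sst_opt Realised optima for this step (default trait
#'   means).
#' @return A list with `z` (densities after the step) and `rates`, a one-row
#'   tibble with `si`, `sst`, `r_pro`, `kc`, `mu_loss` and a list-column
#'   `mu` holding the per-type growth rates.
#' @export
#' @examples
#' p <- model_params()
#' step_symbionts(p$traits$z0, si = 5.5, sst = 27, params = p)
step_symbionts <- function(z, si, sst, params,
                           si_opt = params$traits$si_opt,
                           sst_opt = params$traits$sst_opt) {
  stopifnot(inherits(params, "model_params"),
            length(z) == nrow(params$traits), all(z >= 0))
  total_z <- sum(z)
  r_pro <- resource_allocation(si, total_z, params)
  kc <- env_carrying_capacity(si, sst, params$host)
  mu <- growth_rate(si, sst, r_pro, params$traits, params$c2, si_opt, sst_opt)
  mu_loss <- loss_rate(total_z, kc, params$c3)
  z_next <- z + mu * z - mu_loss * z
  if (any(!is.finite(z_next))) {
    stop("non-finite density produced in step", call. = FALSE)
  }
  list(z = z_next,
       rates = tibble::tibble(si = si, sst = sst, r_pro = r_pro, kc = kc,
                              mu = list(mu), mu_loss = mu_loss))
}

#' Simulate the symbiont community through time
#'
#' Runs the discrete-time optimal-resource model over the configured
#' horizon: at each daily step the seasonal drivers are evaluated (with any
#' thermal-anomaly overlay), each type's optima are redrawn from their
#' phenotypic-variance distributions, and the population balance is applied.
#' The run is bit-reproducible for a fixed seed, and fully deterministic
#' (seed-independent) when all `*_draw_sd` are 0.
#'
#' @param params A [model_params()].
#' @param forcings A [site_forcings()] pair (or any list with
#'   `seasonal_forcing` elements `si` and `sst`).
#' @param anomaly An [anomaly_schedule()] or `NULL` for the baseline run.
#' @param seed Integer master seed: drives the per-type optimum draws and,
#'   in `random_years` mode, the anomaly-year selection.
#' @return A `symbiont_traj` tibble with one row per day `0..horizon_days`.
#'   Row `d` holds the densities `z_<label>` at day `d` and the forcing and
#'   rates (`si`, `sst`, `kc`, `r_pro`, `mu_<label>`, `mu_loss`) used in the
#'   transition from day `d` to `d + 1` (`NA` on the final row). Attributes
#'   `params`, `forcings`, `anomaly` and `seed` record the run.
#' @seealso [summarize_trajectory()], [autoplot.symbiont_traj()]
#' @export
#' @examples
#' traj <- simulate_symbionts(model_params(horizon_days = 360), seed = 1)
#' dplyr::slice_tail(traj, n = 3)
simulate_symbionts <- function(params = model_params(),
                               forcings = site_forcings("lee_stocking"),
                               anomaly = NULL, seed = 1L) {
  stopifnot(inherits(params, "model_params"))
  stopifnot(inherits(forcings$si, "seasonal_forcing"),
            inherits(forcings$sst, "seasonal_forcing"))
  traits <- params$traits
  n_types <- nrow(traits)
  n <- as.integer(params$horizon_days / params$step_days)

  # transition d -> d+1 uses drivers and draws indexed by t = d (d = 0..n-1)
  t_step <- (seq_len(n) - 1) * params$step_days
  years_active <- if (!is.null(anomaly)) {
    select_anomaly_years(anomaly, n_years = max(1L, year_of_day(max(t_step, 0))),
                         seed = seed)
  } else NULL
  si_t <- eval_forcing(forcings$si, t_step)
  sst_t <- eval_sst(forcings$sst, t_step, anomaly, years_active)
  draws <- sample_optima(traits, n, seed = seed)

  k <- params$host$k
  c1 <- params$c1; c2 <- params$c2; c3 <- params$c3
  inv2a2 <- 1 / (2 * traits$si_sd^2)
  inv2b2 <- 1 / (2 * traits$sst_sd^2)
  r_i <- traits$r_i
  h <- params$host

  z <- matrix(NA_real_, n + 1, n_types)
  z[1, ] <- traits$z0
  mu_rec <- matrix(NA_real_, n + 1, n_types)
  kc_rec <- rp_rec <- ml_rec <- si_rec <- sst_rec <- rep(NA_real_, n + 1)

  for (d in seq_len(n)) {
    zc <- z[d, ]
    tz <- sum(zc)
    si <- si_t[d]; sst <- sst_t[d]
    rp <- c1 * si * max(0, 1 - tz / k)
    kc <- k * exp(-(si - h$si_opt)^2 / (2 * h$si_width^2)) *
      exp(-(sst - h$sst_opt)^2 / (2 * h$sst_width^2))
    mu <- c2 * (rp / r_i) *
      exp(-(si - draws$si[d, ])^2 * inv2a2) *
      exp(-(sst - draws$sst[d, ])^2 * inv2b2)
    ml <- if (tz == 0) 0 else min(1, c3 * max(0, tz - kc) / tz)
    zn <- zc + mu * zc - ml * zc
    if (any(!is.finite(zn))) {
      stop(sprintf("non-finite density at step %d", d), call. = FALSE)
    }
    z[d + 1, ] <- zn
    mu_rec[d, ] <- mu
    kc_rec[d] <- kc; rp_rec[d] <- rp; ml_rec[d] <- ml
    si_rec[d] <- si; sst_rec[d] <- sst
  }

  out <- tibble::tibble(day = (0:n) * params$step_days,
                        si = si_rec, sst = sst_rec,
                        kc = kc_rec, r_pro = rp_rec)
  zt <- tibble::as_tibble(as.data.frame(z))
  names(zt) <- paste0("z_", traits$label)
  mt <- tibble::as_tibble(as.data.frame(mu_rec))
  names(mt) <- paste0("mu_", traits$label)
  out <- dplyr::bind_cols(out, zt, mt)
  out$mu_loss <- ml_rec
  structure(out,
            class = c("symbiont_traj", class(out)),
            params = params, forcings = forcings, anomaly = anomaly,
            seed = as.integer(seed))
}

#' @export
print.symbiont_traj <- function(x, ...) {
  p <- attr(x, "params")
  fo <- attr(x, "forcings")
  cat(sprintf("<symbiont_traj> %d types, %d days%s, seed %d\n",
              nrow(p$traits), max(x$day),
              if (!is.null(fo$site)) paste0(", site ", fo$site) else "",
              attr(x, "seed")))
  NextMethod()
}

#' Long (tidy) form of a simulated trajectory
#'
#' @param x A `symbiont_traj` from [simulate_symbionts()].
#' @param ... Unused.
#' @return A tibble with columns `day`, `type`, `density`, `mu` plus the
#'   shared per-step columns `si`, `sst`, `kc`, `r_pro`, `mu_loss`.
#' @export
tidy.symbiont_traj <- function(x, ...) {
  labels <- attr(x, "params")$traits$label
  dens <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(x), "day", dplyr::all_of(paste0("z_", labels))),
    -"day", names_to = "type", values_to = "density",
    names_prefix = "z_")
  mus <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(x), "day", dplyr::all_of(paste0("mu_", labels))),
    -"day", names_to = "type", values_to = "mu",
    names_prefix = "mu_")
  shared <- dplyr::select(tibble::as_tibble(x), "day", "si", "sst", "kc",
                          "r_pro", "mu_loss")
  dplyr::left_join(dplyr::left_join(dens, mus, by = c("day", "type")),
                   shared, by = "day")
}

#' One-row overview of a simulated trajectory
#'
#' @param x A `symbiont_traj`.
#' @param ... Unused.
#' @return A one-row tibble: `n_types`, `horizon_days`, `seed`, `site`,
#'   `final_total` (total density on the last day) and `min_density`
#'   (minimum over all types and days).
#' @export
glance.symbiont_traj <- function(x, ...) {
  labels <- attr(x, "params")$traits$label
  zm <- as.matrix(tibble::as_tibble(x)[paste0("z_", labels)])
  fo <- attr(x, "forcings")
  tibble::tibble(
    n_types = length(labels),
    horizon_days = max(x$day),
    seed = attr(x, "seed"),
    site = fo$site %||% NA_character_,
    final_total = sum(zm[nrow(zm), ]),
    min_density = min(zm))
}
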