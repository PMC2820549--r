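#' Default symbiont trait table
#'
#' The four *Symbiodinium* types of the standard parameterization, as a
#' tibble with one row per type. Types 1 and 3 are specialists (narrow
#' niche, low phenotypic variance); types 2 and 4 are generalists (wide
#' niche). Optima are (SI, SST) = (5.5, 28), (5.5, 26.5), (4.5, 28) and
#' (4.5, 26.5); SI standard deviations are 0.4, 0.8, 0.4, 0.8 and SST
#' standard deviations 0.4, 1, 0.4, 1. All resource requirements `r_i` are 1
#' (equal competitive ability) and every type starts at 1e6 cells cm^-2.
#'
#' Columns: `label`, `si_opt` (kW m^-2 d^-1), `sst_opt` (degC), `si_sd`,
#' `sst_sd` (niche widths, also the per-step sampling SDs of the optima),
#' `r_i` (required resource, dimensionless), `z0` (initial density,
#' cells cm^-2), `role` ("specialist"/"generalist", informational).
#' Optional columns `si_draw_sd`/`sst_draw_sd` override the per-step
#' sampling SDs (set them to 0 for a fully deterministic run in which every
#' draw equals the mean while the Gaussian niche widths stay positive);
#' when absent they default to `si_sd`/`sst_sd`.
#'
#' @return A tibble with 4 rows.
#' @seealso [sample_optima()], [model_params()]
#' @export
default_traits <- function() {
  tibble::tibble(
    label   = paste0("type", 1:4),
    si_opt  = c(5.5, 5.5, 4.5, 4.5),
    sst_opt = c(28, 26.5, 28, 26.5),
    si_sd   = c(0.4, 0.8, 0.4, 0.8),
    sst_sd  = c(0.4, 1.0, 0.4, 1.0),
    r_i     = rep(1, 4),
    z0      = rep(1e6, 4),
    role    = c("specialist", "generalist", "specialist", "generalist"))
}

#' Validate a symbiont trait table
#'
#' Checks the invariants required by the dynamics: unique labels, strictly
#' positive niche widths and resource requirements, non-negative initial
#' densities, finite optima.
#'
#' @param traits A data frame shaped like [default_traits()] (the `role`
#'   column is optional).
#' @return The trait table, invisibly coerced to a tibble, with a `role`
#'   column filled in if missing.
#' @export
validate_traits <- function(traits) {
  stopifnot(is.data.frame(traits))
  need <- c("label", "si_opt", "sst_opt", "si_sd", "sst_sd", "r_i", "z0")
  missing_cols <- setdiff(need, names(traits))
  if (length(missing_cols)) {
    stop("trait table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  traits <- tibble::as_tibble(traits)
  if (nrow(traits) < 1L) stop("trait table is empty", call. = FALSE)
  if (anyDuplicated(traits$label)) {
    stop("trait `label`s must be unique", call. = FALSE)
  }
  for (i in seq_len(nrow(traits))) {
    if (!is.finite(traits$si_opt[i]) || !is.finite(traits$sst_opt[i])) {
      stop(sprintf("traits[%d]: optima must be finite", i), call. = FALSE)
    }
    if (!is.finite(traits$si_sd[i]) || traits$si_sd[i] <= 0) {
      stop(sprintf("traits[%d].si_sd must be > 0", i), call. = FALSE)
    }
    if (!is.finite(traits$sst_sd[i]) || traits$sst_sd[i] <= 0) {
      stop(sprintf("traits[%d].sst_sd must be > 0", i), call. = FALSE)
    }
    if (!is.finite(traits$r_i[i]) || traits$r_i[i] <= 0) {
      stop(sprintf("traits[%d].r_i must be > 0", i), call. = FALSE)
    }
    if (!is.finite(traits$z0[i]) || traits$z0[i] < 0) {
      stop(sprintf("traits[%d].z0 must be >= 0", i), call. = FALSE)
    }
  }
  if (!"si_draw_sd" %in% names(traits)) traits$si_draw_sd <- traits$si_sd
  if (!"sst_draw_sd" %in% names(traits)) traits$sst_draw_sd <- traits$sst_sd
  for (i in seq_len(nrow(traits))) {
    if (!is.finite(traits$si_draw_sd[i]) || traits$si_draw_sd[i] < 0) {
      stop(sprintf("traits[%d].si_draw_sd must be >= 0", i), call. = FALSE)
    }
    if (!is.finite(traits$sst_draw_sd[i]) || traits$sst_draw_sd[i] < 0) {
      stop(sprintf("traits[%d].sst_draw_sd must be >= 0", i), call. = FALSE)
    }
  }
  if (!"role" %in% names(traits)) {
    traits$role <- ifelse(traits$si_sd <= 0.5, "specialist", "generalist")
  }
  traits
}

#' Host niche envelope
#'
#' The coral host's environmental optimum and tolerance, which set the
#' environmentally dependent sustainable density Kc, together with the
#' host-dependent maximum carrying capacity K. Defaults are the standard
#' parameterization: host optima 5.5 kW m^-2 d^-1 (SI) and 27 degC (SST)
#' with tolerance SDs 2.0 and 3.0; K = 5e6 cells cm^-2 (the standard
#' parameterization leaves K free; the default is a calibration value of
#' the same order as the initial total density).
#'
#' @param si_opt Host-optimal solar insolation (kW m^-2 d^-1).
#' @param sst_opt Host-optimal SST (degC).
#' @param si_width Host SI tolerance SD, gamma (kW m^-2 d^-1, > 0).
#' @param sst_width Host SST tolerance SD (degC, > 0).
#' @param k Maximum carrying capacity K (cells cm^-2, > 0).
#' @return An object of class `host_envelope`.
#' @export
host_envelope <- function(si_opt = 5.5, sst_opt = 27,
                          si_width = 2.0, sst_width = 3.0, k = 5e6) {
  if (!is.finite(si_width) || si_width <= 0) {
    stop("host `si_width` must be > 0", call. = FALSE)
  }
  if (!is.finite(sst_width) || sst_width <= 0) {
    stop("host `sst_width` must be > 0", call. = FALSE)
  }
  if (!is.finite(k) || k <= 0) stop("host `k` must be > 0", call. = FALSE)
  stopifnot(is.finite(si_opt), is.finite(sst_opt))
  structure(list(si_opt = si_opt, sst_opt = sst_opt,
                 si_width = si_width, sst_width = sst_width, k = k),
            class = "host_envelope")
}

#' @export
print.host_envelope <- function(x, ...) {
  cat(sprintf(
    "<host_envelope> SI opt %.3g (sd %.3g), SST opt %.3g (sd %.3g), K = %.3g cells cm^-2\n",
    x$si_opt, x$si_width, x$sst_opt, x$sst_width, x$k))
  invisible(x)
}

# deterministic per-type stream seed: depends on the master seed and the
# type label only, so reordering or adding types never perturbs the draws
# of the others (relabeling invariance)
type_stream_seed <- function(master_seed, label) {
  h <- 0
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((as.numeric(master_seed) %% 2147483647 + h * 2654435) %% 2147483647)
}

#' Draw per-step environmental optima for each symbiont type
#'
#' Each iteration step resamples every type's SI and SST optima from normal
#' distributions centred on the trait-table means with the trait-table SDs
#' (the phenotypic-variance mechanism: a generalist's realised optimum
#' wanders more than a specialist's). Each type draws from its own RNG
#' substream, seeded deterministically from `seed` and the type label.
#'
#' @param traits A trait table (see [default_traits()]).
#' @param n_steps Number of iteration steps to draw for.
#' @param seed Master integer seed.
#' @return A list with matrices `si` and `sst`, each `n_steps` x
#'   `nrow(traits)` with type labels as column names.
#' @export
#' @examples
#' d <- sample_optima(default_traits(), 5, seed = 42)
#' d$sst
sample_optima <- function(traits, n_steps, seed = 1L) {
  traits <- validate_traits(traits)
  stopifnot(n_steps >= 0)
  n_types <- nrow(traits)
  si <- matrix(NA_real_, n_steps, n_types,
               dimnames = list(NULL, traits$label))
  sst <- si
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  for (j in seq_len(n_types)) {
    set.seed(type_stream_seed(seed, traits$label[j]))
    if (n_steps > 0) {
      si[, j] <- stats::rnorm(n_steps, traits$si_opt[j], traits$si_draw_sd[j])
      sst[, j] <- stats::rnorm(n_steps, traits$sst_opt[j], traits$sst_draw_sd[j])
    }
  }
  list(si = si, sst = sst)
}
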