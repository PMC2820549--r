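# shared fixtures, built in code

# deterministic traits: optima are never resampled (draw SDs 0) while the
# Gaussian niche widths keep their standard values
deterministic_traits <- function() {
  tr <- default_traits()
  tr$si_draw_sd <- 0
  tr$sst_draw_sd <- 0
  tr
}

# short deterministic parameter set for fast exact tests
det_params <- function(horizon_days = 720, ...) {
  model_params(traits = deterministic_traits(), horizon_days = horizon_days, ...)
}

# constant drivers (amplitude 0)
constant_forcings <- function(si = 5.5, sst = 27) {
  site_forcings("custom",
                si = seasonal_forcing(si, 0, driver = "si"),
                sst = seasonal_forcing(sst, 0, driver = "sst"))
}

# density matrix -> symbiont_traj with the attributes summaries expect
fake_trajectory <- function(z, params = model_params()) {
  stopifnot(ncol(z) == nrow(params$traits))
  n <- nrow(z) - 1
  labels <- params$traits$label
  out <- tibble::tibble(day = 0:n, si = NA_real_, sst = NA_real_,
                        kc = NA_real_, r_pro = NA_real_)
  zt <- tibble::as_tibble(as.data.frame(z))
  names(zt) <- paste0("z_", labels)
  mt <- tibble::as_tibble(as.data.frame(matrix(NA_real_, n + 1, length(labels))))
  names(mt) <- paste0("mu_", labels)
  out <- dplyr::bind_cols(out, zt, mt)
  out$mu_loss <- NA_real_
  structure(out, class = c("symbiont_traj", class(out)),
            params = params, forcings = list(site = "synthetic"),
            anomaly = NULL, seed = 0L)
}

# density columns of a trajectory as a matrix
z_matrix <- function(traj) {
  labels <- attr(traj, "params")$traits$label
  as.matrix(tibble::as_tibble(traj)[paste0("z_", labels)])
}

mu_matrix <- function(traj) {
  labels <- attr(traj, "params")$traits$label
  as.matrix(tibble::as_tibble(traj)[paste0("mu_", labels)])
}
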