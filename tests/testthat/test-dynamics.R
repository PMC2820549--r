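test_that("resource allocation is light times unfilled capacity", {
  p <- model_params(c1 = 0.01)
  k <- p$host$k

  expect_equal(resource_allocation(5.5, k, p), 0)        # saturated host
  expect_equal(resource_allocation(5.5, 0, p), 0.01 * 5.5) # no self-shading
  expect_equal(resource_allocation(5.5, k / 2, p), 0.0275) # closed form
  expect_equal(resource_allocation(5.5, 2 * k, p), 0)    # clamped, not negative

  z <- seq(0, k, length.out = 50)
  expect_true(all(diff(resource_allocation(6, z, p)) <= 0))
})

test_that("the Gaussian growth response peaks at the optima with the stated shape", {
  tr <- default_traits()
  r_pro <- 0.011

  # at both optima the rate is C2 * r_pro / R_i for every type
  mu_peak <- vapply(1:4, function(i) {
    growth_rate(tr$si_opt[i], tr$sst_opt[i], r_pro, tr, c2 = 8)[i]
  }, numeric(1))
  expect_equal(mu_peak, rep(8 * r_pro, 4))

  # symmetric about the optimum on the SI axis
  for (delta in c(0.1, 0.5, 2)) {
    expect_equal(growth_rate(5.5 + delta, 28, r_pro, tr, 8)[1],
                 growth_rate(5.5 - delta, 28, r_pro, tr, 8)[1])
  }

  # one niche width away: peak times exp(-1/2)
  expect_equal(growth_rate(5.5, 28 + tr$sst_sd[1], r_pro, tr, 8)[1],
               8 * r_pro * exp(-0.5))
  expect_equal(growth_rate(5.5 + tr$si_sd[2], 26.5, r_pro, tr, 8)[2],
               8 * r_pro * exp(-0.5))

  # strictly positive whenever resource flows
  expect_true(all(growth_rate(2, 20, 1e-6, tr, 8) > 0))
  expect_equal(growth_rate(2, 20, 0, tr, 8), rep(0, 4))

  bad <- tr; bad$sst_sd[1] <- 0
  expect_error(growth_rate(5.5, 28, r_pro, bad), "sst_sd")
})

test_that("sustainable density Kc is the host-tolerance-weighted capacity", {
  h <- host_envelope()  # optima 5.5 / 27, widths 2 / 3, K = 5e6

  expect_equal(env_carrying_capacity(5.5, 27, h), h$k)
  expect_equal(env_carrying_capacity(5.5, 30, h), h$k * exp(-0.5))
  expect_equal(env_carrying_capacity(7.5, 27, h), h$k * exp(-0.5))

  # monotone decay away from the optimum, bounded by K
  ssts <- 27 + seq(0, 6, by = 0.5)
  kcs <- env_carrying_capacity(5.5, ssts, h)
  expect_true(all(diff(kcs) < 0))
  set.seed(2)
  kc_r <- env_carrying_capacity(stats::runif(200, 0, 10), stats::runif(200, 20, 35), h)
  expect_true(all(kc_r > 0 & kc_r <= h$k))
  expect_true(all(kc_r < h$k | (kc_r == h$k)))
})

test_that("loss removes only the excess over Kc, equally for all types", {
  expect_equal(loss_rate(1e6, 2e6), 0)          # below capacity: no loss
  expect_equal(loss_rate(2e6, 2e6), 0)          # exactly at capacity
  expect_equal(loss_rate(2e6, 1e6, c3 = 1), 0.5) # twice capacity, C3 = 1
  expect_equal(loss_rate(2e6, 1e6, c3 = 100), 1) # capped: lose at most everything
  expect_equal(loss_rate(0, 1e6), 0)            # empty host
  expect_error(loss_rate(1e6, 0), "kc")
  set.seed(3)
  l <- loss_rate(stats::runif(100, 0, 1e7), stats::runif(100, 1, 5e6), c3 = 2)
  expect_true(all(l >= 0 & l <= 1))
})

test_that("a single step reproduces an independent transcription of the balance", {
  p <- det_params()
  si <- 5.5; sst <- 27.5
  z <- rep(1e6, 4)

  # independent, naive evaluation of resource -> growth -> capacity -> loss
  # -> balance with the default constants (C1 = 0.01, C2 = 8, C3 = 1, K = 5e6)
  tz <- 4e6
  rp <- 0.01 * si * (1 - tz / 5e6)
  kc <- 5e6 * exp(-(si - 5.5)^2 / (2 * 2^2)) * exp(-(sst - 27)^2 / (2 * 3^2))
  mu <- 8 * rp *
    exp(-(si - c(5.5, 5.5, 4.5, 4.5))^2 / (2 * c(0.4, 0.8, 0.4, 0.8)^2)) *
    exp(-(sst - c(28, 26.5, 28, 26.5))^2 / (2 * c(0.4, 1, 0.4, 1)^2))
  ml <- min(1, max(0, tz - kc) / tz)
  z_expected <- z + mu * z - ml * z

  got <- step_symbionts(z, si, sst, p)
  expect_equal(got$z, z_expected, tolerance = 1e-12)
  expect_equal(got$rates$r_pro, rp, tolerance = 1e-12)
  expect_equal(got$rates$kc, kc, tolerance = 1e-12)
  expect_equal(got$rates$mu[[1]], mu, tolerance = 1e-12)
  expect_equal(got$rates$mu_loss, ml, tolerance = 1e-12)

  # extinction is absorbing
  expect_equal(step_symbionts(rep(0, 4), si, sst, p)$z, rep(0, 4))
})

test_that("trajectories satisfy the per-step audit identity exactly", {
  traj <- simulate_symbionts(model_params(horizon_days = 720), seed = 17)
  z <- z_matrix(traj)
  mu <- mu_matrix(traj)
  ml <- traj$mu_loss
  n <- nrow(z) - 1
  zc <- z[1:n, , drop = FALSE]
  # identical arithmetic to the update: z + mu*z - ml*z
  expect_true(all(z[2:(n + 1), ] == zc + mu[1:n, ] * zc - ml[1:n] * zc))
  # and the algebraic balance form to floating-point accuracy
  expect_equal(z[2:(n + 1), ], zc * (1 + mu[1:n, ] - ml[1:n]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a deterministic whole run replays the equation chain", {
  p <- det_params(horizon_days = 360)
  fo <- site_forcings("lee_stocking")
  traj <- simulate_symbionts(p, fo, seed = 1)
  tr <- p$traits
  z <- tr$z0
  for (d in 0:359) {
    si <- eval_forcing(fo$si, d); sst <- eval_forcing(fo$sst, d)
    tz <- sum(z)
    rp <- p$c1 * si * max(0, 1 - tz / p$host$k)
    kc <- p$host$k * exp(-(si - 5.5)^2 / 8) * exp(-(sst - 27)^2 / 18)
    mu <- p$c2 * (rp / tr$r_i) *
      exp(-(si - tr$si_opt)^2 / (2 * tr$si_sd^2)) *
      exp(-(sst - tr$sst_opt)^2 / (2 * tr$sst_sd^2))
    ml <- min(1, p$c3 * max(0, tz - kc) / tz)
    z <- z + mu * z - ml * z
    expect_equal(z_matrix(traj)[d + 2, ], z, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("simulation contracts: horizon 0, determinism, non-negativity, bounds", {
  # horizon 0: only the initial state
  t0 <- simulate_symbionts(model_params(horizon_days = 0), seed = 1)
  expect_equal(nrow(t0), 1)
  expect_equal(unname(z_matrix(t0)[1, ]), rep(1e6, 4))

  # same seed, same trajectory (bit-reproducible)
  p <- model_params(horizon_days = 720)
  expect_identical(simulate_symbionts(p, seed = 42),
                   simulate_symbionts(p, seed = 42))

  # zero draw SDs: output independent of the seed
  pd <- det_params(horizon_days = 360)
  expect_equal(simulate_symbionts(pd, seed = 1),
               simulate_symbionts(pd, seed = 999), ignore_attr = TRUE)

  # densities never negative, Kc never above K, loss within [0, 1],
  # and r_pro = 0 whenever the host is saturated (50 seeded short runs)
  p1 <- model_params(horizon_days = 360)
  for (s in 1:50) {
    tr <- simulate_symbionts(p1, seed = s)
    expect_true(min(z_matrix(tr)) >= 0)
    steps <- !is.na(tr$kc)
    expect_true(all(tr$kc[steps] <= p1$host$k))
    expect_true(all(tr$mu_loss[steps] >= 0 & tr$mu_loss[steps] <= 1))
    tot <- rowSums(z_matrix(tr))
    sat <- steps & tot >= p1$host$k
    if (any(sat)) expect_true(all(tr$r_pro[sat] == 0))
  }
})

test_that("permuting the trait table permutes the whole simulation consistently", {
  p <- model_params(horizon_days = 360)
  perm <- c(2, 4, 1, 3)
  tr_perm <- p$traits[perm, ]
  pp <- model_params(traits = tr_perm, horizon_days = 360)
  a <- simulate_symbionts(p, seed = 77)
  b <- simulate_symbionts(pp, seed = 77)
  for (lab in p$traits$label) {
    expect_identical(a[[paste0("z_", lab)]], b[[paste0("z_", lab)]])
  }
  sa <- summarize_trajectory(a)
  sb <- summarize_trajectory(b)
  expect_equal(dplyr::arrange(sa, .data$type), dplyr::arrange(sb, .data$type),
               ignore_attr = TRUE)
})

test_that("tidy and glance views of a trajectory agree with the wide table", {
  traj <- simulate_symbionts(model_params(horizon_days = 90), seed = 8)
  long <- tidy(traj)
  expect_equal(nrow(long), 4 * nrow(traj))
  expect_equal(long$density[long$type == "type2"], traj$z_type2)
  g <- glance(traj)
  expect_equal(g$final_total, sum(z_matrix(traj)[nrow(traj), ]))
  expect_equal(g$horizon_days, 90)
  expect_equal(g$site, "lee_stocking")
})
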