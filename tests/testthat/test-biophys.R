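test_that("particle detection finds sub-pixel centroids above the mass floor", {
  expect_equal(nrow(detect_particles(matrix(0, 40, 40), 9)), 0L)

  # single rendered Gaussian spot at (x=20, y=30) with mild noise
  img <- render_spots(c(60, 60), cbind(20, 30), amplitude = 500,
                      noise_sd = 2, seed = 2)
  det <- detect_particles(img, diameter = 9, mass_threshold = 200)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x - 20), 0.1)
  expect_lt(abs(det$y - 30), 0.1)

  # two spots separated by more than the diameter: both found
  img2 <- render_spots(c(60, 60), rbind(c(20, 30), c(45, 10)),
                       amplitude = 500)
  expect_equal(nrow(detect_particles(img2, 9, 200)), 2L)
  # within separation: merged, the more massive centroid wins
  img3 <- render_spots(c(60, 60), rbind(c(20, 30), c(23, 30)),
                       amplitude = 500)
  det3 <- detect_particles(img3, 9, 200)
  expect_equal(nrow(det3), 1L)

  # below the mass threshold: dropped
  faint <- render_spots(c(60, 60), cbind(20, 30), amplitude = 5)
  expect_equal(nrow(detect_particles(faint, 9, 200)), 0L)

  expect_error(detect_particles(img, diameter = 8),
               class = "solubilome_parameter_error")
  expect_error(detect_particles(img, diameter = 61),
               class = "solubilome_parameter_error")
})

test_that("linking follows drift, avoids swaps, and matches the exhaustive matcher", {
  # single drifting particle -> one full-length track
  d <- do.call(rbind, lapply(0:9, function(f)
    data.frame(frame = f, x = 1 + 0.1 * f, y = 2)))
  lt <- link_tracks(d, max_disp = 0.5)
  expect_equal(length(unique(lt$particle)), 1L)
  expect_equal(nrow(lt), 10L)

  # two stationary well-separated particles -> two tracks, no identity swap
  d2 <- do.call(rbind, lapply(0:9, function(f)
    rbind(data.frame(frame = f, x = 1, y = 1),
          data.frame(frame = f, x = 8, y = 8))))
  lt2 <- link_tracks(d2, max_disp = 1)
  expect_equal(length(unique(lt2$particle)), 2L)
  xs <- tapply(lt2$x, lt2$particle, unique)
  expect_true(all(lengths(xs) == 1))

  # crossing trajectories: assignment equals exhaustive minimal-cost matching
  cross <- rbind(
    data.frame(frame = 0, x = c(0.0, 3.0), y = c(0.0, 0.5)),
    data.frame(frame = 1, x = c(1.0, 2.0), y = c(0.0, 0.5)),
    data.frame(frame = 2, x = c(2.0, 1.0), y = c(0.0, 0.5)),
    data.frame(frame = 3, x = c(3.0, 0.0), y = c(0.0, 0.5)))
  got <- link_tracks(cross, max_disp = 1.6)
  want <- oracle_link(cross, max_disp = 1.6)
  expect_equal(track_partition(got), track_partition(want))

  # memory bridges a gap
  gap <- data.frame(frame = c(0, 1, 3, 4), x = c(1, 1.05, 1.15, 1.2), y = 0)
  expect_equal(length(unique(link_tracks(gap, 0.5, memory = 1)$particle)), 1L)
  expect_equal(length(unique(link_tracks(gap, 0.5, memory = 0)$particle)), 2L)
})

test_that("MSD obeys its closed forms and invariances", {
  # stationary track
  st <- data.frame(particle = 1, frame = 0:9, x_um = 2, y_um = 3)
  expect_true(all(msd_curves(st, fps = 2)$emsd$msd == 0))

  # ballistic track, v = 1 um/s at 2 fps -> MSD(tau) = tau^2
  bal <- data.frame(particle = 1, frame = 0:19, x_um = (0:19) * 0.5, y_um = 0)
  em <- msd_curves(bal, fps = 2)$emsd
  expect_equal(em$msd, em$lag_s^2, tolerance = 1e-12)
  expect_equal(em$msd[em$lag_s == 1], 1)

  # translation and rotation invariance
  set.seed(7)
  tr <- gen_brownian_tracks(0.05, 5, 50, fps = 2, seed = 7)
  base <- msd_curves(tr, fps = 2)$emsd$msd
  shifted <- transform(tr, x_um = x_um + 5, y_um = y_um - 3)
  expect_equal(msd_curves(shifted, fps = 2)$emsd$msd, base, tolerance = 1e-9)
  th <- 0.7
  rotated <- transform(tr, x_um = cos(th) * x_um - sin(th) * y_um,
                       y_um = sin(th) * x_um + cos(th) * y_um)
  expect_equal(msd_curves(rotated, fps = 2)$emsd$msd, base, tolerance = 1e-9)

  # ensemble of N copies of one track equals that track's curve
  copies <- do.call(rbind, lapply(1:4, function(i) transform(bal, particle = i)))
  expect_equal(msd_curves(copies, fps = 2)$emsd$msd, em$msd, tolerance = 1e-12)

  # per-track pair counts decrease with lag
  one <- msd_curves(bal, fps = 2)$imsd
  expect_true(all(diff(one$n_pairs) <= 0))

  # truncation warning when max_lag exceeds the track
  expect_warning(msd_curves(bal, max_lag = 100, fps = 2), "truncat")
})

test_that("diffusion fitting recovers exact and planted coefficients", {
  lags <- seq(0.5, 5, 0.5)
  exact <- data.frame(lag_s = lags, msd = 4 * 0.05 * lags, n_pairs = 100)
  fit <- estimate_diffusion(exact)
  expect_equal(fit$D, 0.05, tolerance = 1e-12)
  expect_false(fit$flagged)

  # ballistic curve: poor linear fit flagged by the residual diagnostic
  bal <- data.frame(lag_s = lags, msd = lags^2, n_pairs = 100)
  expect_true(estimate_diffusion(bal)$flagged)

  expect_error(estimate_diffusion(exact[1, ]), class = "solubilome_domain_error")

  # recovery sweep: planted D over four decades, 50 tracks x 200 frames
  for (i in seq_along(Ds <- c(1e-4, 1e-3, 1e-2, 1e-1))) {
    tk <- gen_brownian_tracks(Ds[i], 50, 200, fps = 2, seed = i)
    em <- msd_curves(tk, fps = 2)$emsd
    D_hat <- estimate_diffusion(em)$D
    expect_lt(abs(D_hat - Ds[i]) / Ds[i], 0.10)
  }
})

test_that("pH calibration fits, inverts and rejects degenerate data", {
  truth <- list(lower = 0.2, upper = 1.4, midpoint = 7.0, slope = 1.1)
  grid <- seq(5, 9, 0.5)
  clean <- data.frame(ph = grid,
                      ratio = truth$lower + (truth$upper - truth$lower) /
                        (1 + exp(-truth$slope * (grid - truth$midpoint))))
  cal <- fit_ph_calibration(clean)
  expect_equal(unlist(cal$coefficients), unlist(truth), tolerance = 1e-6)

  # inverse identity: estimate_ph(curve, curve(pH)) = pH
  expect_equal(estimate_ph(cal, ratio_at_ph(cal, 6.5))$median_ph, 6.5,
               tolerance = 1e-9)
  # ratio at the curve midpoint inverts to the midpoint parameter
  mid_ratio <- (cal$coefficients$lower + cal$coefficients$upper) / 2
  expect_equal(estimate_ph(cal, mid_ratio)$median_ph,
               cal$coefficients$midpoint, tolerance = 1e-9)
  # round trip over the physiological range, noise-free
  for (ph in seq(5.5, 8.5, 0.25))
    expect_lt(abs(estimate_ph(cal, ratio_at_ph(cal, ph))$median_ph - ph), 0.02)

  # blank subtraction convention is shared between fit and inversion
  cal_b <- fit_ph_calibration(transform(clean, ratio = ratio + 0.3), blank = 0.3)
  expect_equal(estimate_ph(cal_b, ratio_at_ph(cal_b, 6.1) + 0.3)$median_ph,
               6.1, tolerance = 1e-6)

  # flat data and non-monotone data are named errors
  expect_error(fit_ph_calibration(data.frame(ph = grid, ratio = 1)),
               "flat", class = "solubilome_fit_error")
  expect_error(fit_ph_calibration(data.frame(ph = grid, ratio = rev(clean$ratio))),
               "monotone", class = "solubilome_fit_error")
  expect_error(fit_ph_calibration(clean[1:4, ]), class = "solubilome_domain_error")

  # out-of-range ratios are clamped and flagged; all-out-of-range errors
  est <- estimate_ph(cal, c(ratio_at_ph(cal, 7), 2.0))
  expect_equal(est$n_clamped, 1L)
  expect_error(estimate_ph(cal, c(1.9, 2.0)), class = "solubilome_domain_error")

  # with calibration noise, inversion still recovers planted pH series
  sim <- gen_ph_calibration_data(noise_cv = 0.02,
                                 sample_ph = c(5.9, 6.2, 7.3, 7.4),
                                 n_cells = 500, cell_cv = 0.05, seed = 6)
  curve <- fit_ph_calibration(sim$calibration)
  est_ph <- vapply(sim$cells, function(r) estimate_ph(curve, r)$median_ph,
                   numeric(1))
  expect_true(all(abs(est_ph - c(5.9, 6.2, 7.3, 7.4)) < 0.1))
})

test_that("growth AUC matches geometry and the analytic logistic integral", {
  lin <- data.frame(time_h = seq(0, 10, 1), od = seq(0, 1, 0.1))
  expect_equal(growth_auc(lin, 10), 5.0)
  flat <- data.frame(time_h = seq(0, 10, 1), od = 0.3)
  expect_equal(growth_auc(flat, 10), 0)
  expect_error(growth_auc(lin, 0.5), class = "solubilome_domain_error")

  # logistic curve vs closed-form integral at dt = 0.1 h
  K <- 1; r <- 0.8; n0 <- 0.01
  tt <- seq(0, 20, 0.1)
  log_curve <- data.frame(time_h = tt,
                          od = K / (1 + ((K - n0) / n0) * exp(-r * tt)))
  expect_lt(abs(growth_auc(log_curve, 20) - oracle_logistic_auc(K, r, n0, 20)) /
            oracle_logistic_auc(K, r, n0, 20), 0.01)
})

test_that("heat-resistance score behaves at the fixed points and monotonically", {
  gc0 <- gen_growth_curves(lag_delta = 0, kill_fraction = 0, noise_sd = 0)
  expect_equal(heat_resistance_score(gc0$treated, gc0$untreated), 1.0)

  dead <- transform(gc0$untreated, od = od[1])
  expect_equal(heat_resistance_score(dead, gc0$untreated), 0.0)

  # score strictly decreasing in the treatment-induced lag
  scores <- vapply(c(0, 1, 2, 4), function(lag) {
    gc <- gen_growth_curves(lag_delta = lag, kill_fraction = 0, noise_sd = 0,
                            seed = 8)
    heat_resistance_score(gc$treated, gc$untreated)
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
  expect_true(all(scores >= 0 & scores <= 1 + 1e-9))

  expect_error(heat_resistance_score(gc0$treated[-1, ], gc0$untreated),
               class = "solubilome_validation_error")
})

test_that("heterogeneity CV and trehalose arithmetic are exact", {
  expect_equal(heterogeneity_cv(rep(3, 10)), 0)
  expect_equal(heterogeneity_cv(c(0, 2)), sqrt(2), tolerance = 1e-12)
  # scale invariance
  set.seed(5)
  px <- runif(100, 0.1, 5)
  expect_equal(heterogeneity_cv(7 * px), heterogeneity_cv(px), tolerance = 1e-12)
  expect_error(heterogeneity_cv(c(0, 0)), class = "solubilome_domain_error")
  expect_error(heterogeneity_cv(3), class = "solubilome_domain_error")

  # focal vs diffuse rendering at matched total intensity
  foci <- gen_cell_image(n_foci = 3, focus_amplitude = 50,
                         diffuse_amplitude = 1, seed = 10)
  diffuse_amp <- 1 + foci$total_signal / sum(foci$mask) -
    sum(gen_cell_image(diffuse_amplitude = 1, seed = 10)$image[foci$mask]) /
    sum(foci$mask)
  diffuse <- gen_cell_image(n_foci = 0, diffuse_amplitude = diffuse_amp,
                            seed = 10)
  expect_equal(diffuse$total_signal, foci$total_signal, tolerance = 1e-6)
  expect_gt(heterogeneity_cv(foci$image[foci$mask]),
            heterogeneity_cv(diffuse$image[diffuse$mask]))

  expect_equal(trehalose_content(5, 1), 4)
  expect_equal(trehalose_content(1, 1), 0)
  expect_warning(z <- trehalose_content(0.9, 1.0), "floor")
  expect_equal(z, 0)
  expect_error(trehalose_content(-1, 0), class = "solubilome_domain_error")
})
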