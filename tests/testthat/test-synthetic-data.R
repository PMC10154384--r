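test_that("all generators are bit-reproducible under a fixed seed", {
  spec <- default_spec()
  mask <- default_mask(spec, 64)
  a <- generate_pillar_video(spec, mask, 1.1, n_frames = 3, noise_sd = 30, seed = 11)
  b <- generate_pillar_video(spec, mask, 1.1, n_frames = 3, noise_sd = 30, seed = 11)
  expect_identical(a$stack, b$stack)
  expect_identical(a$truth$parameters$deflections_um, b$truth$parameters$deflections_um)

  ta <- generate_bead_trajectory(seed = 5)
  tb <- generate_bead_trajectory(seed = 5)
  expect_identical(ta$trajectory$position, tb$trajectory$position)

  ca <- generate_indentation_curve(292, noise_sd = 0.05, seed = 7)
  cb <- generate_indentation_curve(292, noise_sd = 0.05, seed = 7)
  expect_identical(ca$curve$force, cb$curve$force)

  ia <- generate_invasion_stack(below_fraction = 0.5, noise_sd = 20, seed = 9,
                                nx = 32, ny = 32)
  ib <- generate_invasion_stack(below_fraction = 0.5, noise_sd = 20, seed = 9,
                                nx = 32, ny = 32)
  expect_identical(ia$actin, ib$actin)

  ka <- generate_cumulative_counts(10, seed = 3)
  kb <- generate_cumulative_counts(10, seed = 3)
  expect_identical(ka$counts, kb$counts)
})

test_that("zero-force pillar video renders spots exactly on the lattice", {
  spec <- default_spec()
  mask <- default_mask(spec)
  g <- generate_pillar_video(spec, mask, force_scale = 0, n_frames = 2, seed = 1)
  expect_true(all(g$truth$parameters$deflections_um == 0))
  cen <- detect_pillars(g$stack[, , 1], spec)
  nodes <- cbind(g$truth$parameters$node_x_um, g$truth$parameters$node_y_um)
  d <- sqrt(rowSums((as.matrix(cen[, c("x_um", "y_um")]) -
                       nodes[oracle_nearest_assignment(
                         as.matrix(cen[, c("x_um", "y_um")]), nodes, Inf), ])^2))
  expect_lt(max(d) / spec$pixel_size, 0.05)
})

test_that("mean deflection magnitude under the cell is force_scale / k", {
  spec <- default_spec()   # k = 1.36 nN/um
  mask <- default_mask(spec)
  g <- generate_pillar_video(spec, mask, force_scale = 1.36, n_frames = 10,
                             seed = 2)
  under <- g$truth$parameters$under_cell
  defl <- g$truth$parameters$deflections_um
  mags <- sqrt(defl[under, 1, ]^2 + defl[under, 2, ]^2)
  expect_equal(mean(mags), 1.0, tolerance = 1e-10)
})

test_that("unresolvable lattice (pitch below spot diameter) is rejected", {
  expect_error(pillar_array_spec(pitch = 1.5, spot_diameter = 2),
               "unresolvable")
})

test_that("bead amplitude schedule interpolates amp1 to amp1 * relamp12", {
  g1 <- generate_bead_trajectory(amp1 = 2, relamp12 = 1, noise_sd = 0, seed = 1)
  expect_equal(g1$truth$parameters$amplitudes_um, rep(2, 12))
  g2 <- generate_bead_trajectory(amp1 = 2, relamp12 = 0.63, noise_sd = 0, seed = 1)
  amps <- g2$truth$parameters$amplitudes_um
  expect_equal(amps[1], 2)
  expect_equal(amps[12], 0.63 * 2)
  expect_equal(diff(amps), rep(diff(amps)[1], 11))  # linear schedule
  expect_error(generate_bead_trajectory(amp1 = 0), "amp1")
  expect_error(generate_bead_trajectory(frame_rate = 1), "frame_rate")
})

test_that("noiseless trajectory re-extraction matches the stored truth", {
  g <- generate_bead_trajectory(amp1 = 1.5, relamp12 = 0.63, noise_sd = 0,
                                drift = 0, seed = 4)
  prot <- force_protocol()
  amp <- extract_pulse_amplitudes(g$trajectory, prot, t0 = 2)
  truth <- g$truth$parameters$amplitudes_um
  expect_equal(amp$absolute, truth, tolerance = 0.01)
  # and the package path agrees with the naive per-sample oracle
  proj <- as.numeric(g$trajectory$position %*% prot$force_axis)
  for (i in c(1, 6, 12)) {
    expect_equal(amp$absolute[i],
                 oracle_pulse_amplitude(g$trajectory$time, proj, 2, i),
                 tolerance = 1e-12)
  }
})

test_that("synthetic Hertz curve matches the closed form before and after contact", {
  g <- generate_indentation_curve(E_true = 292, R = 7.5, nu = 0.5,
                                  contact_z = 5, z_range = 10, z_step = 0.01,
                                  noise_sd = 0, baseline_slope = 0.1, seed = 1)
  z <- g$curve$z; f <- g$curve$force
  pre <- z <= 5
  expect_equal(f[pre], 0.1 * z[pre], tolerance = 1e-12)
  post <- z > 5
  delta <- z[post] - 5
  expect_equal(f[post],
               0.1 * z[post] + (4 / 3) * (292 / 0.75) * sqrt(7.5) * delta^1.5 * 1e-3,
               tolerance = 1e-12)
  # continuity at contact and linearity in E
  i0 <- which.min(abs(z - 5))
  expect_equal(f[i0], 0.1 * z[i0], tolerance = 1e-12)
  g2 <- generate_indentation_curve(E_true = 584, contact_z = 5, noise_sd = 0,
                                   baseline_slope = 0, seed = 1)
  g1 <- generate_indentation_curve(E_true = 292, contact_z = 5, noise_sd = 0,
                                   baseline_slope = 0, seed = 1)
  expect_equal(g2$curve$force, 2 * g1$curve$force, tolerance = 1e-12)
  expect_error(generate_indentation_curve(292, z_step = 0), "z_step")
})

test_that("invasion stack geometry places the stated fraction below the bilayer", {
  for (f in c(0, 0.54, 1)) {
    g <- generate_invasion_stack(below_fraction = f, nx = 32, ny = 32, seed = 1)
    p <- g$truth$parameters
    expect_equal((p$bilayer_z_um - p$cell_bottom_um) / p$cell_height_um, f)
  }
  expect_error(generate_invasion_stack(below_fraction = 0.5, bilayer_z = 1),
               "outside the stack")
})

test_that("cumulative count generator: zeros, deterministic ramp, slope recovery", {
  g0 <- generate_cumulative_counts(0, days = 5, n_roi = 4, seed = 1)
  expect_true(all(g0$counts$cumulative_count == 0))
  gd <- generate_cumulative_counts(10, days = 5, n_roi = 2, seed = 1,
                                   deterministic = TRUE)
  expect_equal(gd$counts$cumulative_count[gd$counts$roi_id == 1],
               c(10, 20, 30, 40, 50))
  gp <- generate_cumulative_counts(10, days = 5, n_roi = 50, seed = 21)
  fit <- lm(cumulative_count ~ day, data = gp$counts)
  slope <- coef(fit)[["day"]]
  se <- summary(fit)$coefficients["day", "Std. Error"]
  expect_lt(abs(slope - 10), 2 * se)
})

test_that("cohort truth draws match the preset mean and SD (lognormal model)", {
  set.seed(100)
  x <- rlnorm_matched(10000, 1.1, 0.1 * sqrt(70))
  expect_lt(abs(mean(x) - 1.1) / 1.1, 0.02)
  expect_lt(abs(sd(x) - 0.1 * sqrt(70)) / (0.1 * sqrt(70)), 0.03)
  expect_true(all(x > 0))
  b <- rbeta_matched(10000, 0.54, 0.04 * sqrt(19))
  expect_lt(abs(mean(b) - 0.54), 0.01)
  expect_true(all(b > 0 & b < 1))
  expect_equal(rlnorm_matched(5, 2, 0), rep(2, 5))  # sem = 0: identical cells
})

test_that("generate_cohort wires per-cell truths into the per-assay generators", {
  co <- generate_cohort("control", "tweezers", seed = 2, n = 6)
  expect_length(co$cells, 6)
  tr <- co$truth$parameters$per_cell_truths
  for (i in 1:6)
    expect_equal(co$cells[[i]]$truth$parameters$relamp12, tr[i])
  expect_error(generate_cohort("siRARB", "afm", seed = 1),
               "no published")
  ci <- generate_cohort("control", "invasion", seed = 3, n = 3, day = 5,
                        nx = 16, ny = 16)
  f <- ci$truth$parameters$per_cell_truths
  expect_true(all(f > 0 & f < 1))
  expect_equal(ci$cells[[2]]$truth$parameters$below_fraction, f[2])
})
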