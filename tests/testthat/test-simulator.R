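# Blinking-fluorophore EMCCD simulator: geometries, kinetics, rendering,
# block averaging and nearest-neighbour statistics.

test_that("diverging lines: site counts, midpoint separation, coincidence", {
    f <- make_diverging_lines(length_um = 10, max_separation_nm = 350,
                              spacing_nm = 5)
    expect_equal(nrow(f$positions), 2L * 2001L)
    # separation at the axial midpoint is half the maximum
    mid <- f$positions[abs(f$positions[, "y_nm"] - 5000) < 2.5, ]
    expect_equal(diff(range(mid[, "x_nm"])), 175)

    f0 <- make_diverging_lines(length_um = 1, max_separation_nm = 0)
    half <- nrow(f0$positions) / 2
    expect_equal(f0$positions[seq_len(half), ],
                 f0$positions[half + seq_len(half), ])

    f2 <- make_diverging_lines(length_um = 1, spacing_nm = 7)
    expect_equal(nrow(f2$positions), 2L * (floor(1000 / 7) + 1L))
})

test_that("parallel filaments: Poisson labelling, width bound, determinism", {
    n <- replicate(40, nrow(make_parallel_filaments(
        separation_nm = 200, labelling_density_per_um = 21)$positions))
    expect_lt(abs(mean(n) - 84), 3 * sqrt(84) / sqrt(40) * 2)

    f <- make_parallel_filaments(separation_nm = 300,
                                 labelling_density_per_um = 21, seed = 4)
    off <- abs(abs(f$positions[, "x_nm"]) - 150)
    expect_true(all(off <= 0.02 * 317 / 2 + 1e-9))

    f2 <- make_parallel_filaments(separation_nm = 300,
                                  labelling_density_per_um = 21, seed = 4)
    expect_identical(f$positions, f2$positions)
})

test_that("visibility benchmark grid spans the stated ranges", {
    g <- visibility_parameter_grid()
    expect_equal(max(g$separation_nm), 1.1 * 317)
    expect_equal(min(g$separation_nm), 0.1 * 317, tolerance = 1e-12)
    expect_equal(range(g$labelling_density_per_um), c(1, 21))
    expect_equal(range(g$ratio_r), c(0.1, 10))
    expect_true(all(g$k_switch == 0.5))
})

test_that("rates_from_ratio solves the switching-rate constraint", {
    k <- rates_from_ratio(0.5, 1)
    expect_equal(c(1 / k$tau_off_s, 1 / k$tau_on_s), c(1, 1))
    expect_equal(k$k_switch, 0.5)

    k10 <- rates_from_ratio(0.5, 10)
    k_on <- 1 / k10$tau_off_s; k_off <- 1 / k10$tau_on_s
    expect_equal(c(k_on, k_off), c(0.55, 5.5))
    expect_equal(k_on * k_off / (k_on + k_off), 0.5)

    # inverse identity over a grid of (k, r): recomputing k and r from the
    # returned dwell times recovers the inputs
    for (kk in c(0.2, 0.5, 2)) for (rr in c(0.1, 1, 10)) {
        kin <- rates_from_ratio(kk, rr)
        k_on <- 1 / kin$tau_off_s; k_off <- 1 / kin$tau_on_s
        expect_equal(k_on * k_off / (k_on + k_off), kk, tolerance = 1e-12)
        expect_equal(k_off / k_on, rr, tolerance = 1e-12)
    }
    expect_invalid(rates_from_ratio(-1, 2))
})

test_that("blinking is stationary at tau_on/(tau_on + tau_off)", {
    # the five kinetics pairs of the density benchmark
    pairs <- rbind(c(0.6, 6.6), c(0.3, 7.7), c(0.15, 19.85),
                   c(0.1, 39.9), c(0.1, 80))
    expected <- pairs[, 1] / rowSums(pairs)
    expect_equal(expected[c(1, 5)], c(1 / 12, 1 / 800), tolerance = 2e-3)
    for (i in seq_len(nrow(pairs))) {
        kin <- blink_kinetics(pairs[i, 1], pairs[i, 2])
        ne <- 40L; nf <- 2500L  # 1e5 emitter-frames
        onf <- simulate_blinking(kin, ne, nf, 30, seed = 100 + i)
        per <- rowMeans(onf)
        se <- sd(per) / sqrt(ne)
        expect_lt(abs(mean(per) - expected[i]), 3 * se + 0.1 * expected[i])
    }
})

test_that("on-dwell times are exponential with mean tau_on", {
    kin <- blink_kinetics(0.5, 1.5)
    onf <- simulate_blinking(kin, 1L, 60000L, 30, seed = 6)
    x <- onf[1L, ]
    runs <- rle(x > 1 - 1e-9)
    full <- runs$lengths[runs$values]  # fully-on frame runs, ~ tau_on * fps
    est <- (mean(full) + 1) / 30      # run length underestimates by ~1 frame
    se <- sd(full) / sqrt(length(full)) / 30
    expect_lt(abs(est - 0.5), 4 * se)
    # off-time limit: a practically never-on emitter
    never <- simulate_blinking(blink_kinetics(0.5, 1e9), 200L, 50L, 30,
                               seed = 7)
    expect_lt(mean(rowSums(never) > 0), 0.05)
})

test_that("EMCCD conversion chain has the stated dark-frame statistics", {
    cam <- camera_model()
    f <- emitter_field(matrix(0, 1, 2), mean_photon_rate = 1)
    fov <- list(x0_nm = 0, y0_nm = 0, width_px = 100L, height_px = 100L)
    dark <- render_frames(f, matrix(0, 1, 1), cam, seed = 31, fov = fov)
    vals <- dark$frames[, , 1]
    # E = baseline + read_mean + gain * background / sensitivity = 5110
    se <- sd(vals) / 100
    expect_lt(abs(mean(vals) - 5110), 3 * se)

    quiet <- camera_model(background_photons = 0, read_noise_mean_adu = 0,
                          read_noise_sd_adu = 1e-9)
    d0 <- render_frames(f, matrix(0, 1, 1), quiet, seed = 32, fov = fov)
    expect_true(all(d0$frames == 100))
})

test_that("rendering conserves photon flux and the stated rate CV", {
    cam <- camera_model()
    f <- emitter_field(matrix(c(2000, 2000), 1, 2), mean_photon_rate = 3000,
                       rate_cv = 0)
    fov <- list(x0_nm = 0, y0_nm = 0, width_px = 40L, height_px = 40L)
    clean <- render_frames(f, matrix(1, 1, 1), cam, fov = fov, noise = FALSE)
    photons <- sum(clean$frames[, , 1] - cam$baseline_adu -
                   cam$em_gain * cam$background_photons /
                       cam$sensitivity_e_per_adu) /
        (cam$em_gain / cam$sensitivity_e_per_adu)
    expect_lt(abs(photons - 3000 / 30) / (3000 / 30), 0.005)

    # per-frame emitted photons (above the constant background/baseline
    # pedestal) have sd/mean ~ 0.40
    f2 <- emitter_field(matrix(c(2000, 2000), 1, 2), mean_photon_rate = 3000,
                        rate_cv = 0.4)
    st <- render_frames(f2, matrix(1, 1, 500), cam, seed = 33, fov = fov,
                        noise = FALSE)
    pedestal <- cam$baseline_adu + cam$em_gain * cam$background_photons /
        cam$sensitivity_e_per_adu
    tot <- apply(st$frames - pedestal, 3, sum)
    expect_lt(abs(sd(tot) / mean(tot) - 0.4), 0.06)
    expect_invalid(render_frames(f, matrix(1, 3, 2), cam))
})

test_that("peak-SNR calibration is self-consistent and monotone", {
    cam <- camera_model()
    field <- emitter_field(matrix(c(1000, 1000), 1, 2), 1000)
    kin <- blink_kinetics(0.1, 80)
    rate <- calibrate_peak_snr(field, kin, cam, target_snr = 10, seed = 41)
    expect_lt(abs(attr(rate, "snr") - 10) / 10, 0.05)
    expect_true(rate > 1e3 && rate < 1e7)
})

test_that("block averaging: identity, grouping, variance reduction", {
    set.seed(12)
    st <- image_stack(array(rnorm(4 * 4 * 600, mean = 100, sd = 8),
                            dim = c(4, 4, 600)), 100, 1 / 30)
    expect_equal(average_frame_blocks(st, 1)$frames, st$frames)

    av <- average_frame_blocks(st, 100)
    expect_equal(n_frames(av), 6L)
    expect_equal(av$frames[, , 1], rowMeans(st$frames[, , 1:100], dims = 2))
    expect_equal(av$frame_interval_s, 100 / 30)

    # sqrt(n) noise reduction and preserved expectation
    expect_lt(abs(sd(av$frames) / (8 / sqrt(100)) - 1), 0.1)
    expect_equal(rowMeans(av$frames, dims = 2),
                 rowMeans(st$frames[, , 1:600], dims = 2), tolerance = 1e-12)
    expect_invalid(average_frame_blocks(st, 601))
})

test_that("nearest-neighbour distances match hand computations", {
    f <- emitter_field(rbind(c(0, 0), c(80, 0)), 1)
    expect_equal(mean_nearest_neighbour_distance(f, matrix(1, 2, 1)), 80)

    f3 <- emitter_field(rbind(c(0, 0), c(100, 0), c(300, 0)), 1)
    expect_equal(mean_nearest_neighbour_distance(f3, matrix(1, 3, 1)),
                 mean(c(100, 100, 200)))

    # frames without two active emitters are skipped
    onf <- cbind(c(1, 0, 0), c(1, 1, 0))
    expect_equal(mean_nearest_neighbour_distance(f3, onf, on_threshold = 0.5),
                 100)
    expect_error(mean_nearest_neighbour_distance(f3, cbind(c(1, 0, 0))),
                 class = "srrf_undefined_result")
})

test_that("simulated movies are seed-deterministic", {
    field <- make_diverging_lines(length_um = 0.5, max_separation_nm = 100)
    field$mean_photon_rate <- 2e4
    kin <- blink_kinetics(0.6, 6.6)
    m1 <- simulate_movie(field, kin, n_frames = 8, seed = 55)
    m2 <- simulate_movie(field, kin, n_frames = 8, seed = 55)
    expect_identical(m1$stack$frames, m2$stack$frames)
    expect_identical(m1$on_fractions, m2$on_fractions)
    m3 <- simulate_movie(field, kin, n_frames = 8, seed = 56)
    expect_false(identical(m1$stack$frames, m3$stack$frames))
})
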