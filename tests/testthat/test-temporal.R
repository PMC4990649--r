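# Temporal collapse of radiality stacks: mean, pairwise correlation,
# auto-cumulants, and the full reconstruction pipeline.

stack_of <- function(...) {
    ms <- list(...)
    array(unlist(ms), dim = c(dim(ms[[1]]), length(ms)))
}

test_that("temporal mean: identical maps, cancellation, CLT shrinkage", {
    a <- matrix(rnorm(25), 5, 5)
    expect_equal(temporal_mean(stack_of(a, a, a))$values, a)
    expect_equal(temporal_mean(stack_of(a, -a))$values, matrix(0, 5, 5))

    set.seed(7)
    tt <- 1000
    noise <- array(rnorm(16 * tt, sd = 0.3), dim = c(4, 4, tt))
    m <- temporal_mean(noise)$values
    expect_true(all(abs(m) < 5 * 0.3 / sqrt(tt)))
})

test_that("pairwise correlation: constant stacks, variance, noise nulls", {
    a <- matrix(2.5, 3, 3)
    expect_equal(temporal_pairwise_correlation(stack_of(a, a, a), 1)$values,
                 matrix(0, 3, 3))

    two <- stack_of(matrix(0, 2, 2), matrix(2, 2, 2))
    expect_equal(temporal_pairwise_correlation(two, 0)$values,
                 matrix(1, 2, 2))  # population variance of {0, 2}

    set.seed(8)
    tt <- 2000
    noise <- array(rnorm(9 * tt), dim = c(3, 3, tt))
    v <- temporal_pairwise_correlation(noise, 1)$values
    # lag-1 products have variance ~ 1/T; all pixels within 4 sigma of 0
    expect_true(all(abs(v) < 4 / sqrt(tt)))

    expect_invalid(temporal_pairwise_correlation(two, 2))
})

test_that("cumulants: constants vanish, two-point series, Gaussian nulls", {
    a <- matrix(1.3, 3, 3)
    for (ord in 2:4)
        expect_equal(temporal_cumulant(stack_of(a, a, a, a), ord)$values,
                     matrix(0, 3, 3))

    pm <- stack_of(matrix(-1, 2, 2), matrix(1, 2, 2),
                   matrix(-1, 2, 2), matrix(1, 2, 2))
    expect_equal(temporal_cumulant(pm, 2)$values, matrix(1, 2, 2))
    expect_equal(temporal_cumulant(pm, 3)$values, matrix(0, 2, 2))
    expect_equal(temporal_cumulant(pm, 4)$values, matrix(-2, 2, 2))

    set.seed(9)
    tt <- 1e4
    g <- array(rnorm(4 * tt), dim = c(2, 2, tt))
    k3 <- temporal_cumulant(g, 3)$values
    k4 <- temporal_cumulant(g, 4)$values
    se3 <- sqrt(6 / tt); se4 <- sqrt(96 / tt)
    expect_true(all(abs(k3) < 5 * se3))
    expect_true(all(abs(k4) < 5 * se4))

    expect_invalid(temporal_cumulant(stack_of(a, a), 3))
})

test_that("single-frame reconstruction with mean equals weighted radiality", {
    f <- gaussian_frame(15, c(7.2, 7.6)) * 50 + 3
    st <- image_stack(f, pixel_size_nm = 100, frame_interval_s = 1 / 30)
    rset <- radiality_settings(magnification = 5L)
    img <- srrf_reconstruct(st, rset, temporal_settings("mean"))
    w <- weight_radiality(radiality_frame(f, rset), f, settings = rset)
    expect_equal(img$values, w$values)
    expect_equal(img$pixel_size_nm, 20)
})

test_that("streamed lagged correlation matches the in-memory operation", {
    set.seed(10)
    tt <- 30
    frames <- array(rexp(11 * 11 * tt), dim = c(11, 11, tt)) +
        array(rep(gaussian_frame(11, c(5.5, 5.5)) * 20, tt),
              dim = c(11, 11, tt))
    st <- image_stack(frames, 100, 1 / 30)
    rset <- radiality_settings(magnification = 2L)
    for (lag in c(0L, 1L, 3L)) {
        img <- srrf_reconstruct(st, rset,
                                temporal_settings("pairwise_correlation",
                                                  lag_frames = lag))
        maps <- sapply(seq_len(tt), function(t) {
            f <- frames[, , t]
            weight_radiality(radiality_frame(f, rset), f,
                             settings = rset)$values
        }, simplify = "array")
        ref <- temporal_pairwise_correlation(maps, lag)
        expect_equal(img$values, ref$values, tolerance = 1e-12)
    }
})

test_that("streamed cumulants match the in-memory operations", {
    set.seed(11)
    tt <- 25
    frames <- array(rexp(9 * 9 * tt, rate = 0.2), dim = c(9, 9, tt))
    st <- image_stack(frames, 100, 1 / 30)
    rset <- radiality_settings(magnification = 2L)
    maps <- sapply(seq_len(tt), function(t) {
        f <- frames[, , t]
        weight_radiality(radiality_frame(f, rset), f, settings = rset)$values
    }, simplify = "array")
    for (ord in 2:4) {
        img <- srrf_reconstruct(st, rset, temporal_settings("cumulant",
                                                            order = ord))
        ref <- temporal_cumulant(maps, ord)
        expect_equal(img$values, ref$values, tolerance = 1e-10)
    }
})

test_that("pair of fluctuating fluorophores separated by sigma is resolved", {
    # two emitters 135 nm apart (the widefield PSF sigma): the mean image
    # is diffraction-limited into one blob, the SRRF image shows two
    cam <- camera_model()
    field <- emitter_field(rbind(c(-67.5, 0), c(67.5, 0)),
                           mean_photon_rate = 6e4)
    kin <- blink_kinetics(0.2, 0.8)  # mostly one emitter on at a time
    movie <- simulate_movie(field, kin, cam, n_frames = 100, seed = 21)
    img <- srrf_reconstruct(movie$stack,
                            radiality_settings(magnification = 10L),
                            temporal_settings("pairwise_correlation"))
    fov <- movie$stack$metadata$fov
    xc <- (seq_len(ncol(img$values)) - 0.5) * img$pixel_size_nm + fov$x0_nm
    rows <- abs((seq_len(nrow(img$values)) - 0.5) * img$pixel_size_nm +
                fov$y0_nm) < 100
    cols <- abs(xc) < 250
    prof <- data.frame(position_nm = xc[cols],
                       intensity = colMeans(img$values[rows, cols]))
    sp <- sparrow_resolved(prof)
    expect_true(sp$resolved)
    # the apparent separation of an overlapping pair is pulled inward
    expect_lt(abs(sp$separation_nm - 135), 80)

    dl <- temporal_mean(movie$stack$frames, 100)
    xs <- (seq_len(ncol(dl$values)) - 0.5) * 100 + fov$x0_nm
    rs <- abs((seq_len(nrow(dl$values)) - 0.5) * 100 + fov$y0_nm) < 150
    pd <- data.frame(position_nm = xs[abs(xs) < 400],
                     intensity = colMeans(dl$values[rs, abs(xs) < 400]))
    expect_false(sparrow_resolved(pd)$resolved)
})

test_that("background of the correlation image decays with stack length", {
    cam <- camera_model()
    dark_field <- emitter_field(matrix(0, 1, 2), mean_photon_rate = 1)
    fov <- list(x0_nm = 0, y0_nm = 0, width_px = 16L, height_px = 16L)
    rset <- radiality_settings(magnification = 2L)
    # lag-1 correlation of temporally independent noise: the background
    # magnitude shrinks like 1/sqrt(T)
    bg <- sapply(c(100L, 400L, 1600L), function(tt) {
        st <- render_frames(dark_field, matrix(0, 1, tt), cam, seed = 61,
                            fov = fov)
        img <- srrf_reconstruct(st, rset,
                                temporal_settings("pairwise_correlation",
                                                  lag_frames = 1L))
        mean(abs(img$values))
    })
    expect_true(all(diff(bg) < 0))
})

test_that("dark-stack correlation is far below a single-emitter peak", {
    cam <- camera_model()
    fov <- list(x0_nm = 0, y0_nm = 0, width_px = 16L, height_px = 16L)
    rset <- radiality_settings(magnification = 2L)
    tt <- 500L
    dark <- render_frames(emitter_field(matrix(0, 1, 2), 1),
                          matrix(0, 1, tt), cam, seed = 62, fov = fov)
    di <- srrf_reconstruct(dark, rset,
                           temporal_settings("pairwise_correlation",
                                             lag_frames = 1L))
    one <- emitter_field(matrix(c(800, 800), 1, 2), mean_photon_rate = 6e4)
    onf <- simulate_blinking(blink_kinetics(0.2, 0.8), 1L, tt, seed = 63)
    lit <- render_frames(one, onf, cam, seed = 64, fov = fov)
    li <- srrf_reconstruct(lit, rset,
                           temporal_settings("pairwise_correlation",
                                             lag_frames = 1L))
    expect_lt(quantile(abs(di$values), 0.99), 0.01 * max(li$values))
})

test_that("mean-method peak positions are brightness-invariant", {
    cam <- camera_model()
    fov <- list(x0_nm = 0, y0_nm = 0, width_px = 16L, height_px = 16L)
    rset <- radiality_settings(magnification = 5L)
    peak_of <- function(rate) {
        f <- emitter_field(matrix(c(790, 780), 1, 2),
                           mean_photon_rate = rate)
        st <- render_frames(f, matrix(1, 1, 60), cam, seed = 65, fov = fov)
        img <- srrf_reconstruct(st, rset, temporal_settings("mean"))
        which(img$values == max(img$values), arr.ind = TRUE)[1L, ]
    }
    p1 <- peak_of(3e4)
    p2 <- peak_of(6e4)
    expect_lte(max(abs(p1 - p2)), 1)  # within one fine pixel
})
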