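# Analytic fixtures shared across the suite.

PSF_SIGMA_PX <- 1.35                       # 135 nm on 100 nm pixels
GAUSS_FWHM <- 2 * sqrt(2 * log(2))         # FWHM in units of sigma

# Frame of summed isotropic Gaussians; centers is an n x 2 matrix of
# (x, y) in pixel units (pixel (i, j) spans [i-1, i) x [j-1, j)).
gaussian_frame <- function(side, centers, sigma = PSF_SIGMA_PX,
                           amplitudes = 1, sigma_y = sigma) {
    centers <- matrix(centers, ncol = 2L)
    amplitudes <- rep_len(amplitudes, nrow(centers))
    xs <- seq_len(side) - 0.5
    f <- matrix(0, side, side)
    for (i in seq_len(nrow(centers)))
        f <- f + amplitudes[i] *
            outer(xs, xs, function(y, x)
                exp(-(x - centers[i, 1L])^2 / (2 * sigma^2) -
                     (y - centers[i, 2L])^2 / (2 * sigma_y^2)))
    f
}

# Analytic gradient field of one isotropic Gaussian, sampled at pixel centres.
gaussian_gradient <- function(side, cx, cy, sigma = PSF_SIGMA_PX) {
    xs <- seq_len(side) - 0.5
    g <- outer(xs, xs, function(y, x)
        exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2)))
    list(gx = outer(xs, xs, function(y, x)
             -(x - cx) / sigma^2 *
                 exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2))),
         gy = outer(xs, xs, function(y, x)
             -(y - cy) / sigma^2 *
                 exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2))),
         intensity = g)
}

# Central profile of a radiality map along x, averaged over the two fine
# rows bracketing y = yc (in source-pixel units).
central_profile <- function(map, yc) {
    m <- map$settings$magnification
    a <- round(yc * m)
    vals <- colMeans(map$values[c(a, a + 1L), , drop = FALSE])
    data.frame(position_nm = (seq_len(ncol(map$values)) - 0.5) / m,
               intensity = vals)
}

# FWHM of a single-peak profile by linear interpolation.
profile_fwhm <- function(x, y) {
    i <- which.max(y)
    half <- y[i] / 2
    left <- approx(y[1:i], x[1:i], xout = half, ties = "ordered")$y
    right <- approx(rev(y[i:length(y)]), rev(x[i:length(y)]), xout = half,
                    ties = "ordered")$y
    right - left
}

expect_invalid <- function(expr) expect_error(expr, class = "srrf_invalid_input")
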