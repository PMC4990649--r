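#' Fluorophore ground-truth field
#'
#' @param positions `n x 2` matrix of `(x, y)` positions in nm.
#' @param mean_photon_rate mean emission rate, photons per second.
#' @param rate_cv per-frame emission-rate coefficient of variation
#'   (s.d. as a fraction of the mean; default 0.4).
#' @param geometry_label free-text description of the geometry.
#' @param geometry optional named list with geometric metadata.
#' @return An object of class `emitter_field`.
#' @export
emitter_field <- function(positions, mean_photon_rate = 1000, rate_cv = 0.4,
                          geometry_label = "", geometry = list()) {
    positions <- as.matrix(positions)
    if (ncol(positions) != 2L || !all(is.finite(positions)))
        .invalid("positions must be a finite n x 2 matrix (x, y) in nm")
    if (mean_photon_rate <= 0) .invalid("mean_photon_rate must be positive")
    if (rate_cv < 0) .invalid("rate_cv must be non-negative")
    colnames(positions) <- c("x_nm", "y_nm")
    structure(list(positions = positions,
                   mean_photon_rate = as.numeric(mean_photon_rate),
                   rate_cv = as.numeric(rate_cv),
                   geometry_label = geometry_label, geometry = geometry),
              class = "emitter_field")
}

#' @export
print.emitter_field <- function(x, ...) {
    cat(sprintf("emitter_field: %d emitters (%s), %.4g photons/s (cv %.2g)\n",
                nrow(x$positions), x$geometry_label, x$mean_photon_rate,
                x$rate_cv))
    invisible(x)
}

#' Two-state blinking kinetics
#'
#' Exponentially distributed on- and off-dwell times of a continuous-time
#' two-state Markov emitter.  Derived quantities: the stationary on-state
#' probability `p_on = tau_on / (tau_on + tau_off)` and the mean switching
#' rate `k = k_on * k_off / (k_on + k_off)` with `k_on = 1 / tau_off`,
#' `k_off = 1 / tau_on`.
#'
#' @param tau_on_s mean on-time in seconds.
#' @param tau_off_s mean off-time in seconds.
#' @return A list of class `blink_kinetics` with the derived `p_on` and
#'   `k_switch` included.
#' @export
blink_kinetics <- function(tau_on_s, tau_off_s) {
    if (tau_on_s <= 0 || tau_off_s <= 0)
        .invalid("tau_on_s and tau_off_s must be positive")
    k_on <- 1 / tau_off_s
    k_off <- 1 / tau_on_s
    structure(list(tau_on_s = tau_on_s, tau_off_s = tau_off_s,
                   p_on = tau_on_s / (tau_on_s + tau_off_s),
                   k_switch = k_on * k_off / (k_on + k_off)),
              class = "blink_kinetics")
}

#' Kinetics from switching rate and off/on rate ratio
#'
#' Solves for `(k_on, k_off)` given the mean switching rate
#' `k = k_on * k_off / (k_on + k_off)` and the ratio `k_off / k_on = r`:
#' `k_on = k * (1 + r) / r`, `k_off = k * (1 + r)`.
#'
#' @param k_switch mean switching rate, 1/s.
#' @param ratio_r dimensionless off/on rate ratio.
#' @return A [blink_kinetics()] object.
#' @export
rates_from_ratio <- function(k_switch, ratio_r) {
    if (k_switch <= 0 || ratio_r <= 0)
        .invalid("k_switch and ratio_r must be positive")
    k_on <- k_switch * (1 + ratio_r) / ratio_r
    k_off <- k_switch * (1 + ratio_r)
    blink_kinetics(tau_on_s = 1 / k_off, tau_off_s = 1 / k_on)
}

#' EMCCD camera model
#'
#' Conversion chain from expected photons to A/D counts:
#' photons + background are Poisson-sampled, multiplied by the linear EM
#' gain, divided by the sensitivity (photoelectrons per ADU), offset by
#' the baseline, and Gaussian read noise is added; the result is rounded
#' and clipped at zero.
#'
#' @param pixel_size_nm camera pixel pitch (default 100 nm).
#' @param psf_sigma_nm Gaussian PSF standard deviation (default 135 nm).
#' @param lattice_nm rendering lattice pitch (default 10 nm; must divide
#'   the pixel size).
#' @param background_photons mean background photons per pixel per frame.
#' @param em_gain linear electron-multiplying gain.
#' @param sensitivity_e_per_adu photoelectrons per A/D count.
#' @param baseline_adu camera base level in ADU.
#' @param read_noise_mean_adu,read_noise_sd_adu Gaussian read noise (ADU).
#' @param frame_rate_fps acquisition frame rate, frames per second.
#' @return A list of class `camera_model`.
#' @export
camera_model <- function(pixel_size_nm = 100, psf_sigma_nm = 135,
                         lattice_nm = 10, background_photons = 100,
                         em_gain = 100, sensitivity_e_per_adu = 2,
                         baseline_adu = 100, read_noise_mean_adu = 10,
                         read_noise_sd_adu = 3, frame_rate_fps = 30) {
    vals <- c(pixel_size_nm, psf_sigma_nm, lattice_nm, em_gain,
              sensitivity_e_per_adu, frame_rate_fps)
    if (any(vals <= 0)) .invalid("camera parameters must be positive")
    if (abs(pixel_size_nm / lattice_nm - round(pixel_size_nm / lattice_nm)) >
        1e-9)
        .invalid("pixel_size_nm must be an integer multiple of lattice_nm")
    structure(list(pixel_size_nm = pixel_size_nm, psf_sigma_nm = psf_sigma_nm,
                   lattice_nm = lattice_nm,
                   background_photons = background_photons, em_gain = em_gain,
                   sensitivity_e_per_adu = sensitivity_e_per_adu,
                   baseline_adu = baseline_adu,
                   read_noise_mean_adu = read_noise_mean_adu,
                   read_noise_sd_adu = read_noise_sd_adu,
                   frame_rate_fps = frame_rate_fps),
              class = "camera_model")
}

#' Diverging two-line test structure
#'
#' Two lines whose separation grows linearly from 0 at one end to
#' `max_separation_nm` at the other, with emitter sites every
#' `spacing_nm` along each line.  The lines run along y; the structure is
#' centred on x = 0 and starts at y = 0.
#'
#' @param length_um line length in micrometres (default 10).
#' @param max_separation_nm separation at the far end (default 350 nm).
#' @param spacing_nm emitter spacing along each line (default 5 nm).
#' @param mean_photon_rate,rate_cv emission parameters, see
#'   [emitter_field()].
#' @return An `emitter_field` with `floor(length / spacing) + 1` sites per
#'   line; `geometry` records `length_nm`, `max_separation_nm` and the
#'   per-emitter line id.
#' @export
make_diverging_lines <- function(length_um = 10, max_separation_nm = 350,
                                 spacing_nm = 5, mean_photon_rate = 1000,
                                 rate_cv = 0.4) {
    if (spacing_nm <= 0) .invalid("spacing_nm must be positive")
    length_nm <- length_um * 1000
    y <- seq(0, length_nm, by = spacing_nm)
    sep <- max_separation_nm * y / length_nm
    pos <- rbind(cbind(-sep / 2, y), cbind(sep / 2, y))
    emitter_field(pos, mean_photon_rate, rate_cv,
                  geometry_label = "diverging lines",
                  geometry = list(length_nm = length_nm,
                                  max_separation_nm = max_separation_nm,
                                  spacing_nm = spacing_nm,
                                  line_id = rep(1:2, each = length(y)),
                                  center_x_nm = 0))
}

#' Randomly labelled parallel filaments
#'
#' Two parallel filaments of fixed length, each a narrow band
#' `width_fwhm_fraction * fwhm_nm` wide, labelled with a Poisson number of
#' fluorophores (mean `labelling_density_per_um * length_um` per filament)
#' placed uniformly along the filament with a uniform transverse offset
#' within the band.  Filaments run along y at `x = -separation/2` and
#' `x = +separation/2`.
#'
#' @param length_um filament length (default 2).
#' @param separation_nm centre-to-centre filament separation.
#' @param width_fwhm_fraction band width as a fraction of `fwhm_nm`.
#' @param labelling_density_per_um mean fluorophores per micrometre.
#' @param fwhm_nm PSF full width at half maximum (default 317 nm).
#' @param seed optional RNG seed for reproducible placement.
#' @param mean_photon_rate,rate_cv emission parameters.
#' @return An `emitter_field`.
#' @export
make_parallel_filaments <- function(length_um = 2, separation_nm,
                                    width_fwhm_fraction = 0.02,
                                    labelling_density_per_um,
                                    fwhm_nm = 317, seed = NULL,
                                    mean_photon_rate = 1000, rate_cv = 0.4) {
    if (labelling_density_per_um <= 0) .invalid("density must be positive")
    if (!is.null(seed)) set.seed(seed)
    width <- width_fwhm_fraction * fwhm_nm
    length_nm <- length_um * 1000
    one <- function(xc) {
        n <- rpois(1L, labelling_density_per_um * length_um)
        cbind(xc + runif(n, -width / 2, width / 2), runif(n, 0, length_nm))
    }
    pos <- rbind(one(-separation_nm / 2), one(separation_nm / 2))
    if (nrow(pos) == 0L) pos <- matrix(numeric(0), 0L, 2L)
    emitter_field(pos, mean_photon_rate, rate_cv,
                  geometry_label = "parallel filaments",
                  geometry = list(length_nm = length_nm,
                                  separation_nm = separation_nm,
                                  fwhm_nm = fwhm_nm, width_nm = width,
                                  center_x_nm = 0))
}

#' Parameter grid of the two-filament visibility benchmark
#'
#' The benchmark sweeps filament separation from 0.1 to 1.1 times the PSF
#' FWHM (317 nm, i.e. 31.7 nm to 348.7 nm), labelling density from 1 to
#' 21 per micrometre, the off/on rate ratio from 0.1 to 10, the mean
#' emission rate from 100 to 10,000 photons/s and the background from 0 to
#' 50% of the emission rate, holding the mean switching rate at half the
#' frame rate of 1 f.p.s.  Grid granularity within those printed ranges is
#' a package choice.
#'
#' @param fwhm_nm PSF full width at half maximum (default 317 nm).
#' @return A data.frame with one row per parameter combination and
#'   columns `separation_nm`, `labelling_density_per_um`, `ratio_r`,
#'   `mean_photon_rate`, `background_fraction`, `k_switch`.
#' @export
visibility_parameter_grid <- function(fwhm_nm = 317) {
    g <- expand.grid(
        separation_nm = (1:11) * fwhm_nm / 10,
        labelling_density_per_um = c(1, 2, 5, 11, 21),
        ratio_r = 10^seq(-1, 1, by = 0.5),
        mean_photon_rate = 10^seq(2, 4, by = 1),
        background_fraction = c(0, 0.25, 0.5),
        KEEP.OUT.ATTRS = FALSE)
    g$k_switch <- 0.5
    g
}

#' Simulate two-state blinking on-fractions
#'
#' Exact event-driven simulation of a continuous-time two-state Markov
#' process per emitter, not synchronized with the frame clock.  The
#' initial state is drawn from the stationary distribution
#' (`p_on = tau_on / (tau_on + tau_off)`); dwell times are exponential.
#' Each frame's entry is the fraction of the frame time spent emitting.
#'
#' @param kinetics a [blink_kinetics()] object.
#' @param n_emitters number of independent emitters.
#' @param n_frames number of frames (>= 1).
#' @param frame_rate_fps frame rate (default 30).
#' @param seed optional RNG seed.
#' @return `n_emitters x n_frames` matrix of on-fractions in `[0, 1]`.
#' @export
simulate_blinking <- function(kinetics, n_emitters, n_frames,
                              frame_rate_fps = 30, seed = NULL) {
    if (n_frames < 1L) .invalid("n_frames must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    t_total <- n_frames / frame_rate_fps
    out <- matrix(0, n_emitters, n_frames)
    for (e in seq_len(n_emitters)) {
        iv <- .blink_intervals(kinetics, t_total)
        if (nrow(iv) > 0L)
            out[e, ] <- .interval_frame_overlap(iv, n_frames, frame_rate_fps)
    }
    out
}

# On-intervals (start, end) of one emitter over [0, t_total].
.blink_intervals <- function(kin, t_total) {
    state <- runif(1L) < kin$p_on
    times <- numeric(0)
    elapsed <- 0
    s <- state
    n_guess <- max(16L, ceiling(4 * t_total /
                                (kin$tau_on_s + kin$tau_off_s)) + 8L)
    while (elapsed < t_total) {
        k <- seq_len(n_guess)
        means <- ifelse(xor(s, k %% 2L == 0L), kin$tau_on_s, kin$tau_off_s)
        d <- rexp(n_guess) * means
        times <- c(times, d)
        elapsed <- elapsed + sum(d)
        s <- xor(s, n_guess %% 2L == 1L)
    }
    bounds <- cumsum(times)
    starts <- c(0, bounds[-length(bounds)])
    on <- rep(c(state, !state), length.out = length(times))
    keep <- on & starts < t_total
    if (!any(keep)) return(matrix(numeric(0), 0L, 2L))
    cbind(starts[keep], pmin(bounds[keep], t_total))
}

# Per-frame overlap fractions of on-intervals with the frame grid.
.interval_frame_overlap <- function(iv, n_frames, fps) {
    frac <- numeric(n_frames)
    dt <- 1 / fps
    for (i in seq_len(nrow(iv))) {
        a <- iv[i, 1L]; b <- iv[i, 2L]
        i0 <- max(1L, floor(a * fps) + 1L)
        i1 <- min(n_frames, floor(b * fps - 1e-12) + 1L)
        if (i1 < i0) next
        idx <- i0:i1
        frac[idx] <- frac[idx] +
            (pmin(b, idx * dt) - pmax(a, (idx - 1L) * dt)) / dt
    }
    pmin(frac, 1)
}

# Binned 1-D Gaussian PSF mass per camera pixel: density evaluated at
# lattice-cell centres times the lattice pitch, summed within each pixel.
.binned_psf_1d <- function(center_nm, px0_nm, n_px, cam) {
    lat <- cam$lattice_nm
    per <- as.integer(round(cam$pixel_size_nm / lat))
    xl <- px0_nm + (seq_len(n_px * per) - 0.5) * lat
    v <- dnorm(xl, mean = center_nm, sd = cam$psf_sigma_nm) * lat
    rowsum_grp <- rep(seq_len(n_px), each = per)
    as.numeric(rowsum(v, rowsum_grp))
}

#' Field of view helper
#'
#' Bounding box of an emitter field expanded by a pixel margin and
#' snapped to the camera pixel grid.
#'
#' @param field an [emitter_field()].
#' @param cam a [camera_model()].
#' @param margin_px margin in camera pixels on each side.
#' @return list with `x0_nm`, `y0_nm` (field-of-view origin) and integer
#'   `width_px`, `height_px`.
#' @export
default_fov <- function(field, cam, margin_px = 6L) {
    px <- cam$pixel_size_nm
    x0 <- floor(min(field$positions[, 1L]) / px - margin_px) * px
    y0 <- floor(min(field$positions[, 2L]) / px - margin_px) * px
    w <- ceiling(max(field$positions[, 1L]) / px + margin_px) - x0 / px
    h <- ceiling(max(field$positions[, 2L]) / px + margin_px) - y0 / px
    list(x0_nm = x0, y0_nm = y0, width_px = as.integer(w),
         height_px = as.integer(h))
}

#' Render camera frames from an emitter field
#'
#' For each frame, every active emitter draws a per-frame emission rate
#' from a normal distribution (s.d. `rate_cv * mean`, floored at 0); its
#' expected photon count is `rate * on_fraction / frame_rate`.  The
#' Gaussian PSF is evaluated on the high-resolution lattice and summed
#' into camera pixels, background photons are added, photon shot noise is
#' Poisson-sampled, and the EMCCD conversion
#' `baseline + round(gain * n_e / sensitivity) + read noise` is applied;
#' final values are rounded and clipped at zero.
#'
#' @param field an [emitter_field()].
#' @param on_fractions `n_emitters x n_frames` matrix from
#'   [simulate_blinking()] (or ones for always-on emitters).
#' @param camera a [camera_model()].
#' @param seed optional RNG seed.
#' @param fov optional field of view from [default_fov()].
#' @param noise apply the Poisson/EMCCD noise chain (disable to obtain
#'   noise-free expected images plus baseline).
#' @return An [image_stack()] in ADU with the simulation recorded in
#'   `metadata`.
#' @export
render_frames <- function(field, on_fractions, camera = camera_model(),
                          seed = NULL, fov = NULL, noise = TRUE) {
    if (nrow(field$positions) != nrow(on_fractions) &&
        nrow(field$positions) > 0L)
        .invalid("on_fractions rows must match the emitter count")
    if (!is.null(seed)) set.seed(seed)
    if (is.null(fov)) fov <- default_fov(field, camera)
    h <- fov$height_px; w <- fov$width_px
    n_fr <- ncol(on_fractions)
    fps <- camera$frame_rate_fps
    px <- camera$pixel_size_nm
    n_em <- nrow(field$positions)
    win <- ceiling(4 * camera$psf_sigma_nm / px)
    frames <- array(0, dim = c(h, w, n_fr))
    for (t in seq_len(n_fr)) {
        img <- matrix(0, h, w)
        act <- which(on_fractions[, t] > 0)
        if (length(act) > 0L) {
            rates <- pmax(0, rnorm(length(act), field$mean_photon_rate,
                                   field$rate_cv * field$mean_photon_rate))
            for (i in seq_along(act)) {
                e <- act[i]
                photons <- rates[i] * on_fractions[e, t] / fps
                if (photons <= 0) next
                ex <- field$positions[e, 1L]; ey <- field$positions[e, 2L]
                jc <- floor((ex - fov$x0_nm) / px)  # 0-based pixel
                ic <- floor((ey - fov$y0_nm) / px)
                j0 <- max(0L, jc - win); j1 <- min(w - 1L, jc + win)
                i0 <- max(0L, ic - win); i1 <- min(h - 1L, ic + win)
                if (j1 < j0 || i1 < i0) next
                bx <- .binned_psf_1d(ex, fov$x0_nm + j0 * px, j1 - j0 + 1L,
                                     camera)
                by <- .binned_psf_1d(ey, fov$y0_nm + i0 * px, i1 - i0 + 1L,
                                     camera)
                img[(i0 + 1L):(i1 + 1L), (j0 + 1L):(j1 + 1L)] <-
                    img[(i0 + 1L):(i1 + 1L), (j0 + 1L):(j1 + 1L)] +
                    photons * outer(by, bx)
            }
        }
        if (noise) {
            ne <- rpois(h * w, img + camera$background_photons)
            adu <- camera$baseline_adu +
                round(camera$em_gain * ne / camera$sensitivity_e_per_adu) +
                rnorm(h * w, camera$read_noise_mean_adu,
                      camera$read_noise_sd_adu)
            frames[, , t] <- matrix(pmax(0, round(adu)), h, w)
        } else {
            frames[, , t] <- camera$baseline_adu +
                camera$em_gain * (img + camera$background_photons) /
                camera$sensitivity_e_per_adu
        }
    }
    image_stack(frames, pixel_size_nm = px, frame_interval_s = 1 / fps,
                metadata = list(fov = fov, camera = unclass(camera),
                                geometry = field$geometry,
                                geometry_label = field$geometry_label,
                                seed = seed))
}

#' Calibrate the emission rate to a target peak SNR
#'
#' Finds, by bisection on the mean photon emission rate, the rate at which
#' the single-frame peak signal-to-noise ratio matches `target_snr`.  The
#' peak SNR is the expected peak ADU above background divided by the
#' Monte-Carlo standard deviation of that pixel's value over `n_mc`
#' rendered frames of a single always-on emitter.
#'
#' @param field an [emitter_field()]; the emitter closest to the field
#'   centroid defines the measurement position.
#' @param kinetics a [blink_kinetics()] object (kept for provenance; the
#'   calibration frames use a fully emitting fluorophore at constant rate,
#'   which is what "peak" single-frame SNR refers to).
#' @param camera a [camera_model()].
#' @param target_snr target peak SNR (default 10).
#' @param seed RNG seed.
#' @param n_mc Monte-Carlo frames per SNR measurement (>= 200).
#' @param tol relative tolerance on the achieved SNR (default 0.05).
#' @return calibrated mean photon rate (photons/s), with the measured SNR
#'   attached as attribute `snr`.
#' @export
calibrate_peak_snr <- function(field, kinetics, camera = camera_model(),
                               target_snr = 10, seed = 1L, n_mc = 200L,
                               tol = 0.05) {
    if (nrow(field$positions) < 1L) .invalid("field must contain an emitter")
    ctr <- colMeans(field$positions)
    e <- which.min((field$positions[, 1L] - ctr[1L])^2 +
                   (field$positions[, 2L] - ctr[2L])^2)
    # rate_cv is excluded from the probe: peak SNR characterizes the
    # shot/camera noise at the mean emission rate, and a 40% rate CV would
    # otherwise cap the measurable SNR at 1/CV regardless of brightness
    probe <- emitter_field(field$positions[e, , drop = FALSE],
                           mean_photon_rate = 1, rate_cv = 0)
    px <- camera$pixel_size_nm
    # peak camera pixel PSF mass (deterministic)
    fov <- default_fov(probe, camera)
    bx <- .binned_psf_1d(probe$positions[1L, 1L], fov$x0_nm, fov$width_px,
                         camera)
    by <- .binned_psf_1d(probe$positions[1L, 2L], fov$y0_nm, fov$height_px,
                         camera)
    mass <- outer(by, bx)
    peak <- which(mass == max(mass), arr.ind = TRUE)[1L, ]
    gain_adu <- camera$em_gain / camera$sensitivity_e_per_adu
    measure <- function(rate) {
        probe$mean_photon_rate <- rate
        st <- render_frames(probe,
                            matrix(1, 1L, n_mc), camera, seed = seed,
                            fov = fov)
        vals <- st$frames[peak[1L], peak[2L], ]
        expected_signal <- gain_adu * (rate / camera$frame_rate_fps) *
            max(mass)
        expected_signal / sd(vals)
    }
    lo <- 1; hi <- 1e4
    while (measure(hi) < target_snr && hi < 1e9) hi <- hi * 10
    s_lo <- measure(lo)
    if (s_lo > target_snr)
        .undefined("SNR bracket failure: lower bound already exceeds target",
                   data = list(rate_lo = lo, snr_lo = s_lo))
    for (it in seq_len(60L)) {
        mid <- sqrt(lo * hi)
        s <- measure(mid)
        if (abs(s - target_snr) / target_snr <= tol) {
            return(structure(mid, snr = s))
        }
        if (s < target_snr) lo <- mid else hi <- mid
    }
    .undefined("peak-SNR bisection did not converge",
               data = list(lo = lo, hi = hi))
}

#' Average non-overlapping frame blocks
#'
#' Collapses consecutive blocks of `block` frames into their pixel-wise
#' mean, emulating high-density acquisitions produced by temporal
#' averaging of a low-density sequence; averaging n frames reduces the
#' background standard deviation by about sqrt(n).  A trailing partial
#' block is dropped; the frame interval is multiplied by `block`.
#'
#' @param stack an [image_stack()].
#' @param block block size (>= 1, <= number of frames).
#' @return An [image_stack()] with `floor(T / block)` frames.
#' @export
average_frame_blocks <- function(stack, block) {
    tt <- n_frames(stack)
    if (block < 1L || block > tt)
        .invalid("block must satisfy 1 <= block <= n frames")
    block <- as.integer(block)
    nb <- tt %/% block
    d <- dim(stack$frames)
    a <- stack$frames[, , seq_len(nb * block), drop = FALSE]
    dim(a) <- c(d[1L] * d[2L], block, nb)
    out <- array(apply(a, 3L, rowMeans), dim = c(d[1L], d[2L], nb))
    image_stack(out, stack$pixel_size_nm, stack$frame_interval_s * block,
                c(stack$metadata, list(block_average = block)))
}

#' Mean within-frame nearest-neighbour distance
#'
#' For each frame, emitters whose on-fraction exceeds `on_threshold` form
#' the active set; each active emitter contributes its Euclidean distance
#' to the nearest active neighbour.  The result pools these distances over
#' all frames with at least two active emitters.
#'
#' @param field an [emitter_field()].
#' @param on_fractions `n_emitters x n_frames` on-fraction matrix.
#' @param on_threshold minimum on-fraction counting as "emitting".  The
#'   default 0 counts a fluorophore that emits at any point during the
#'   frame, which is what deposits signal in that frame's image; raise it
#'   to mimic detectability thresholds of localization software (short
#'   sub-frame flashes are then discarded, which matters at sparse
#'   kinetics).
#' @return mean nearest-neighbour distance in nm.
#' @export
mean_nearest_neighbour_distance <- function(field, on_fractions,
                                            on_threshold = 0) {
    pos <- field$positions
    total <- 0; count <- 0L
    for (t in seq_len(ncol(on_fractions))) {
        act <- which(on_fractions[, t] > on_threshold)
        n <- length(act)
        if (n < 2L) next
        dm <- as.matrix(dist(pos[act, , drop = FALSE]))
        diag(dm) <- Inf
        nn <- apply(dm, 1L, min)
        total <- total + sum(nn)
        count <- count + n
    }
    if (count == 0L)
        .undefined("no frame contains two simultaneously emitting fluorophores")
    total / count
}

#' One-call ground-truth movie simulation
#'
#' Convenience wrapper: blinking simulation plus frame rendering with a
#' shared seed, returning the stack together with its ground truth.
#'
#' @param field an [emitter_field()].
#' @param kinetics a [blink_kinetics()] object.
#' @param camera a [camera_model()].
#' @param n_frames number of frames.
#' @param seed RNG seed (distinct sub-streams for kinetics and noise).
#' @param fov optional field of view.
#' @return list of class `ground_truth_movie`: `stack`, `on_fractions`,
#'   `field`, `kinetics`, `camera`, `seed`.
#' @export
simulate_movie <- function(field, kinetics, camera = camera_model(),
                           n_frames = 100L, seed = 1L, fov = NULL) {
    onf <- simulate_blinking(kinetics, nrow(field$positions), n_frames,
                             camera$frame_rate_fps, seed = seed)
    stack <- render_frames(field, onf, camera, seed = seed + 1L, fov = fov)
    structure(list(stack = stack, on_fractions = onf, field = field,
                   kinetics = kinetics, camera = camera, seed = seed),
              class = "ground_truth_movie")
}
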