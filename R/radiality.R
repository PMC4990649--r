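#' Radiality transform settings
#'
#' Parameters of the sub-pixel gradient-convergence (radiality) transform.
#' `ring_radius_px` is the radius, in source-pixel units, of the sampling
#' ring on which gradient convergence towards each sub-pixel centre is
#' measured; `n_ring_samples` points are placed on it at equal angles.
#' The transform is evaluated on a grid magnified `magnification`-fold.
#'
#' @param ring_radius_px ring radius in source pixels (0.1 to 5).
#' @param n_ring_samples integer number of ring samples (>= 4).
#' @param magnification integer sub-pixel magnification (>= 1).
#' @param do_intensity_weighting multiply the radiality map by the
#'   interpolated, background-subtracted frame intensity.
#' @param do_gradient_weighting multiply by the ring-mean gradient
#'   magnitude normalized to the frame maximum.
#' @param clamp_negative set negative (divergent) radiality to zero.
#' @param sensitivity exponent applied to the radiality values
#'   (sign-preserving, `sign(R) * |R|^sensitivity`).  A monotone
#'   transform: it never creates or destroys peaks, but narrows the
#'   radiality cone, trading contrast for sharpness like the sensitivity
#'   control of established radiality tools.  Default 1 (off).
#' @return A list of class `radiality_settings`.
#' @export
radiality_settings <- function(ring_radius_px = 0.5, n_ring_samples = 8L,
                               magnification = 5L,
                               do_intensity_weighting = TRUE,
                               do_gradient_weighting = TRUE,
                               clamp_negative = TRUE,
                               sensitivity = 1) {
    if (ring_radius_px < 0.1 || ring_radius_px > 5)
        .invalid("ring_radius_px must lie in [0.1, 5] source pixels")
    if (n_ring_samples < 4L) .invalid("n_ring_samples must be >= 4")
    if (magnification < 1L) .invalid("magnification must be >= 1")
    if (sensitivity <= 0) .invalid("sensitivity must be positive")
    structure(list(ring_radius_px = as.numeric(ring_radius_px),
                   n_ring_samples = as.integer(n_ring_samples),
                   magnification = as.integer(magnification),
                   do_intensity_weighting = isTRUE(do_intensity_weighting),
                   do_gradient_weighting = isTRUE(do_gradient_weighting),
                   clamp_negative = isTRUE(clamp_negative),
                   sensitivity = as.numeric(sensitivity)),
              class = "radiality_settings")
}

#' Image gradient by finite differences
#'
#' Centred differences in the interior, one-sided differences at the
#' borders.  With x along columns and y along rows, a ramp
#' `f(x, y) = 2x + 3y` yields `gx = 2`, `gy = 3` exactly in the interior.
#'
#' @param frame numeric matrix, at least 3 x 3.
#' @return list with matrices `gx` and `gy`, same dimensions as `frame`.
#' @export
compute_gradient <- function(frame) {
    if (!is.matrix(frame) || nrow(frame) < 3L || ncol(frame) < 3L)
        .invalid("frame must be a matrix of at least 3 x 3 pixels")
    nr <- nrow(frame); nc <- ncol(frame)
    gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
    gx[, 2:(nc - 1L)] <- (frame[, 3:nc] - frame[, 1:(nc - 2L)]) / 2
    gx[, 1L] <- frame[, 2L] - frame[, 1L]
    gx[, nc] <- frame[, nc] - frame[, nc - 1L]
    gy[2:(nr - 1L), ] <- (frame[3:nr, ] - frame[1:(nr - 2L), ]) / 2
    gy[1L, ] <- frame[2L, ] - frame[1L, ]
    gy[nr, ] <- frame[nr, ] - frame[nr - 1L, ]
    list(gx = gx, gy = gy)
}

#' Equally spaced points on a sampling ring
#'
#' @param center numeric length-2 position `c(x, y)` in source-pixel units.
#' @param r ring radius.
#' @param n number of samples (>= 4); sample `i` sits at angle
#'   `2 * pi * (i - 1) / n`, the first at angle zero.
#' @return an `n x 2` matrix of `(x, y)` positions.
#' @export
sample_ring <- function(center, r, n) {
    if (n < 4L) .invalid("n must be >= 4")
    th <- 2 * pi * (seq_len(n) - 1L) / n
    cbind(x = center[1L] + r * cos(th), y = center[2L] + r * sin(th))
}

.as_radiality_map <- function(values, settings, pixel_size_nm = NA_real_,
                              ring_gmag = NULL) {
    structure(list(values = values,
                   pixel_size_nm = pixel_size_nm /
                       settings$magnification,
                   settings = settings, ring_gmag = ring_gmag),
              class = "radiality_map")
}

#' Radiality transform of a gradient field
#'
#' Low-level entry point used by [radiality_frame()]; also accepts
#' analytically constructed gradient fields, which makes the perfect
#' convergence case (radiality exactly 1 at the centre of a radially
#' symmetric peak) directly testable.
#'
#' @param gx,gy gradient component matrices sampled at pixel centres.
#' @param settings a [radiality_settings()] object.
#' @param pixel_size_nm optional source pixel size carried to the output.
#' @return A `radiality_map`: `values` on the magnified grid, the
#'   magnified pixel size, and the ring-mean gradient magnitude map.
#' @export
radiality_map_from_gradient <- function(gx, gy, settings = radiality_settings(),
                                        pixel_size_nm = NA_real_) {
    if (!identical(dim(gx), dim(gy)))
        .invalid("gx and gy must have identical dimensions")
    res <- cpp_radiality(gx, gy, settings$ring_radius_px,
                         settings$n_ring_samples, settings$magnification)
    v <- res$radiality
    if (settings$sensitivity != 1)
        v <- sign(v) * abs(v)^settings$sensitivity
    .as_radiality_map(v, settings, pixel_size_nm,
                      ring_gmag = res$ring_gmag)
}

#' Sub-pixel radiality transform of a single frame
#'
#' Computes the finite-difference gradient field of the frame and, for
#' every centre on the `magnification`-fold magnified grid, measures the
#' convergence of the (bicubically interpolated) gradient directions on a
#' ring of radius `ring_radius_px`: each ring point contributes
#' `s * (1 - min(d, r) / r)` where `d` is the perpendicular distance from
#' the centre to the line through the ring point along its gradient and
#' `s` is +1 when the gradient points towards the centre, -1 otherwise.
#' The mean over ring points lies in `[-1, 1]`; it is 1 at the centre of a
#' perfectly radially symmetric peak, 0 on flat fields, and independent of
#' any positive rescaling of the frame.
#'
#' @param frame numeric matrix (>= 3 x 3).
#' @param settings a [radiality_settings()] object.
#' @param pixel_size_nm optional source pixel size (nm).
#' @return A `radiality_map` (unweighted, unclamped).
#' @export
radiality_frame <- function(frame, settings = radiality_settings(),
                            pixel_size_nm = NA_real_) {
    g <- compute_gradient(frame)
    radiality_map_from_gradient(g$gx, g$gy, settings, pixel_size_nm)
}

#' Intensity and gradient weighting of a radiality map
#'
#' De-noises a raw radiality map by multiplying it with the interpolated
#' frame intensity (median-subtracted, floored at zero) and/or the
#' ring-mean gradient magnitude normalized by the frame's maximum gradient
#' magnitude.  With both weights off and clamping off this is the
#' identity.
#'
#' @param raw a `radiality_map` produced from `frame` with `settings`.
#' @param frame the source frame.
#' @param gradients optional precomputed [compute_gradient()] output.
#' @param settings the [radiality_settings()] in force.
#' @return A weighted `radiality_map`.
#' @export
weight_radiality <- function(raw, frame, gradients = NULL,
                             settings = raw$settings) {
    m <- settings$magnification
    if (!identical(dim(raw$values), dim(frame) * m))
        .invalid("radiality map dimensions do not match frame * magnification")
    v <- raw$values
    if (settings$do_intensity_weighting) {
        bg <- pmax(frame - median(frame), 0)
        v <- v * cpp_magnify_bicubic(bg, m)
    }
    if (settings$do_gradient_weighting) {
        if (is.null(gradients)) gradients <- compute_gradient(frame)
        gmax <- max(sqrt(gradients$gx^2 + gradients$gy^2))
        if (gmax > 0) {
            rg <- raw$ring_gmag
            if (is.null(rg)) {
                res <- cpp_radiality(gradients$gx, gradients$gy,
                                     settings$ring_radius_px,
                                     settings$n_ring_samples, m)
                rg <- res$ring_gmag
            }
            v <- v * (rg / gmax)
        } else {
            v <- v * 0
        }
    }
    if (settings$clamp_negative) v <- pmax(v, 0)
    out <- raw
    out$values <- v
    out$settings <- settings
    out
}

#' @export
print.radiality_map <- function(x, ...) {
    d <- dim(x$values)
    cat(sprintf("radiality_map: %d x %d (M = %d, r = %.3g px, N = %d)\n",
                d[1L], d[2L], x$settings$magnification,
                x$settings$ring_radius_px, x$settings$n_ring_samples))
    invisible(x)
}
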