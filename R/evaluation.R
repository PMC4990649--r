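#' Fourier ring correlation between two images
#'
#' Both images are Fourier transformed; concentric annuli one pixel wide
#' (integer radius, by rounding) are segmented in frequency space and the
#' normalized cross-correlation between corresponding rings is computed:
#' `FRC(q) = Re(sum(Fa * conj(Fb))) / sqrt(sum(|Fa|^2) * sum(|Fb|^2))`.
#' Ring radius `q` maps to spatial frequency `q / (side * pixel_size)`.
#'
#' @param img_a,img_b square numeric matrices of identical dimensions
#'   (use [crop_pow2_square()] first for the conventional crop).
#' @param pixel_size_nm pixel size of the images in nm.
#' @param threshold resolution threshold stored with the curve
#'   (default 1/7).
#' @return An object of class `frc_curve`: data.frame with `radius`,
#'   `spatial_frequency` (1/nm) and `correlation`, plus attributes
#'   `threshold`, `side` and `pixel_size_nm`.
#' @export
frc_curve <- function(img_a, img_b, pixel_size_nm, threshold = 1 / 7) {
    if (is.list(img_a) && !is.null(img_a$values)) img_a <- img_a$values
    if (is.list(img_b) && !is.null(img_b$values)) img_b <- img_b$values
    if (!identical(dim(img_a), dim(img_b)))
        .invalid("images must have identical dimensions")
    if (nrow(img_a) != ncol(img_a)) .invalid("images must be square")
    n <- nrow(img_a)
    fa <- fft(img_a)
    fb <- fft(img_b)
    k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))[seq_len(n)]
    rad <- round(sqrt(outer(k^2, k^2, `+`)))
    keep <- rad <= n %/% 2
    grp <- factor(rad[keep], levels = 0:(n %/% 2))
    num <- rowsum(Re(fa[keep] * Conj(fb[keep])), grp)
    da <- rowsum(Mod(fa[keep])^2, grp)
    db <- rowsum(Mod(fb[keep])^2, grp)
    corr <- as.numeric(num) / sqrt(as.numeric(da) * as.numeric(db))
    corr[!is.finite(corr)] <- 0
    radius <- 0:(n %/% 2)
    out <- data.frame(radius = radius,
                      spatial_frequency = radius / (n * pixel_size_nm),
                      correlation = corr)
    structure(out, class = c("frc_curve", "data.frame"),
              threshold = threshold, side = n, pixel_size_nm = pixel_size_nm)
}

#' Resolution from an FRC curve
#'
#' The resolution is the reciprocal of the spatial frequency at which the
#' (unsmoothed) curve first falls below the threshold, with sub-ring
#' precision by linear interpolation between the last ring above and the
#' first ring below.  The DC ring is excluded from the search.
#'
#' @param curve an [frc_curve()].
#' @param threshold correlation threshold (default 1/7).
#' @return resolution in nm.
#' @export
frc_resolution <- function(curve, threshold = 1 / 7) {
    cc <- curve$correlation[-1L]
    ff <- curve$spatial_frequency[-1L]
    below <- which(cc < threshold)
    if (length(below) == 0L)
        .undefined("FRC never falls below the threshold", data = curve)
    i <- below[1L]
    if (i == 1L) return(1 / ff[1L])
    y1 <- cc[i - 1L]; y2 <- cc[i]
    f1 <- ff[i - 1L]; f2 <- ff[i]
    fc <- f1 + (y1 - threshold) / (y1 - y2) * (f2 - f1)
    1 / fc
}

#' LOESS display smoothing of an FRC curve
#'
#' Local linear regression (bandwidth as a fraction of the rings,
#' robustness iterations 0) used for display only; threshold crossings
#' are always determined on the unsmoothed curve.
#'
#' @param curve an [frc_curve()].
#' @param bandwidth smoother span (default 0.0707).
#' @param robustness number of robustness iterations (default 0).
#' @return the curve with an added `smoothed` column.
#' @export
frc_smooth <- function(curve, bandwidth = 0.0707, robustness = 0L) {
    if (nrow(curve) < 5L) .invalid("need at least 5 rings to smooth")
    sm <- lowess(curve$spatial_frequency, curve$correlation,
                 f = bandwidth, iter = robustness)
    curve$smoothed <- sm$y
    curve
}

#' Centred power-of-two square crop
#'
#' Crops an image to the largest centred square whose side is a power of
#' two, the conventional input region for Fourier ring correlation.
#'
#' @param img numeric matrix (both sides >= 2).
#' @return cropped matrix of side `2^floor(log2(min(dim(img))))`.
#' @export
crop_pow2_square <- function(img) {
    if (is.list(img) && !is.null(img$values)) img <- img$values
    if (min(dim(img)) < 2L) .invalid("image sides must be >= 2")
    side <- 2^floor(log2(min(dim(img))))
    r0 <- (nrow(img) - side) %/% 2L
    c0 <- (ncol(img) - side) %/% 2L
    img[(r0 + 1L):(r0 + side), (c0 + 1L):(c0 + side), drop = FALSE]
}

.bilinear <- function(img, y, x) {
    # y, x in pixel units; pixel (i, j) centre at (i - 0.5, j - 0.5)
    nr <- nrow(img); nc <- ncol(img)
    u <- pmin(pmax(y - 0.5, 0), nr - 1)
    v <- pmin(pmax(x - 0.5, 0), nc - 1)
    i0 <- pmin(floor(u), nr - 2); i1 <- i0 + 1
    j0 <- pmin(floor(v), nc - 2); j1 <- j0 + 1
    fy <- u - i0; fx <- v - j0
    img[cbind(i0 + 1, j0 + 1)] * (1 - fy) * (1 - fx) +
        img[cbind(i1 + 1, j0 + 1)] * fy * (1 - fx) +
        img[cbind(i0 + 1, j1 + 1)] * (1 - fy) * fx +
        img[cbind(i1 + 1, j1 + 1)] * fy * fx
}

#' Band-averaged intensity profile along a line
#'
#' Samples the image (bilinearly) along the segment `p0 -> p1` and
#' averages over equally spaced transverse offsets spanning a band of
#' `band_width_nm`, which keeps the profile from being dominated by
#' single-pixel noise peaks.
#'
#' @param img numeric matrix or an `srrf_image`.
#' @param pixel_size_nm image pixel size (nm).
#' @param p0,p1 segment endpoints, `c(x, y)` in nm measured from the
#'   image origin (top-left corner).
#' @param band_width_nm full transverse averaging band (default 100 nm;
#'   0 means a single unaveraged profile).
#' @param step_nm sampling step along the line (default half a pixel).
#' @return An object of class `line_profile`: data.frame with
#'   `position_nm` (distance from `p0`) and `intensity`, plus attribute
#'   `band_width_nm`.
#' @export
extract_line_profile <- function(img, pixel_size_nm, p0, p1,
                                 band_width_nm = 100,
                                 step_nm = pixel_size_nm / 2) {
    if (is.list(img) && !is.null(img$values)) {
        if (!is.null(img$pixel_size_nm) && is.na(pixel_size_nm))
            pixel_size_nm <- img$pixel_size_nm
        img <- img$values
    }
    lims <- c(ncol(img), nrow(img)) * pixel_size_nm
    for (p in list(p0, p1))
        if (any(p < 0) || p[1L] > lims[1L] || p[2L] > lims[2L])
            .invalid("profile endpoints must lie inside the image")
    len <- sqrt(sum((p1 - p0)^2))
    n <- max(2L, floor(len / step_nm) + 1L)
    s <- seq(0, len, length.out = n)
    dir <- (p1 - p0) / len
    nrm <- c(-dir[2L], dir[1L])
    if (band_width_nm > 0) {
        noff <- max(1L, 2L * floor(band_width_nm / 2 / step_nm) + 1L)
        offs <- seq(-band_width_nm / 2, band_width_nm / 2, length.out = noff)
    } else offs <- 0
    acc <- numeric(n)
    for (o in offs) {
        xs <- (p0[1L] + s * dir[1L] + o * nrm[1L]) / pixel_size_nm
        ys <- (p0[2L] + s * dir[2L] + o * nrm[2L]) / pixel_size_nm
        acc <- acc + .bilinear(img, ys, xs)
    }
    out <- data.frame(position_nm = s, intensity = acc / length(offs))
    structure(out, class = c("line_profile", "data.frame"),
              band_width_nm = band_width_nm)
}

# indices of local maxima (plateaus count once, at their centre)
.local_maxima <- function(y) {
    r <- rle(y)
    n <- length(r$values)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    out <- integer(0)
    for (i in seq_len(n)) {
        left_ok <- i == 1L || r$values[i - 1L] < r$values[i]
        right_ok <- i == n || r$values[i + 1L] < r$values[i]
        if (left_ok && right_ok && !(i == 1L && i == n))
            out <- c(out, (starts[i] + ends[i]) %/% 2L)
    }
    out
}

#' Sparrow criterion on a line profile
#'
#' Two structures are considered resolved once a noticeable dip appears
#' between their intensity peaks: the profile must contain two local
#' maxima with an interior local minimum at least
#' `min_dip_fraction * (smaller maximum)` below the smaller maximum.  The
#' two highest local maxima are used.
#'
#' @param profile a [extract_line_profile()] result (or a data.frame with
#'   `position_nm` and `intensity`).
#' @param min_dip_fraction minimal relative dip (default 0.01).
#' @return list with `resolved` (logical), `separation_nm` (distance
#'   between the two maxima when resolved, otherwise `NA`), `peaks_nm`
#'   (positions) and `dip_fraction`.
#' @export
sparrow_resolved <- function(profile, min_dip_fraction = 0.01) {
    y <- profile$intensity
    x <- profile$position_nm
    if (length(y) < 5L) .invalid("profile must contain at least 5 points")
    unresolved <- list(resolved = FALSE, separation_nm = NA_real_,
                       peaks_nm = NA_real_, dip_fraction = NA_real_)
    mx <- .local_maxima(y)
    if (length(mx) < 2L) return(unresolved)
    mx <- mx[order(y[mx], decreasing = TRUE)][1:2]
    mx <- sort(mx)
    inner <- y[mx[1L]:mx[2L]]
    dipv <- min(inner)
    smaller <- min(y[mx])
    dip_fraction <- if (smaller > 0) (smaller - dipv) / smaller else NA_real_
    if (!is.na(dip_fraction) && dip_fraction >= min_dip_fraction)
        list(resolved = TRUE, separation_nm = abs(x[mx[2L]] - x[mx[1L]]),
             peaks_nm = x[mx], dip_fraction = dip_fraction)
    else unresolved
}

#' Normalized two-peak visibility
#'
#' `V = (sqrt(I_max1 * I_max2) - I_min) / sqrt(I_max1 * I_max2)`, clamped
#' at -1: 1 means complete separation (`I_min = 0`), 0 means no contrast,
#' negative values mean the midpoint is brighter than the peaks.
#'
#' @param i_max1,i_max2 intensities at the two known structure positions
#'   (must be positive).
#' @param i_min intensity at their midpoint.
#' @return list of class `visibility_result` with `I_max1`, `I_max2`,
#'   `I_min` and `V`.
#' @export
visibility <- function(i_max1, i_max2, i_min) {
    if (i_max1 <= 0 || i_max2 <= 0)
        .invalid("peak intensities must be positive")
    g <- sqrt(i_max1 * i_max2)
    structure(list(I_max1 = i_max1, I_max2 = i_max2, I_min = i_min,
                   V = max((g - i_min) / g, -1)),
              class = "visibility_result")
}

#' Visibility read from a profile at known structure positions
#'
#' Intensities are interpolated from the profile at the two known
#' positions and at their midpoint, then passed to [visibility()].
#'
#' @param profile a [extract_line_profile()] result.
#' @param pos1_nm,pos2_nm known structure positions along the profile.
#' @return A `visibility_result`.
#' @export
visibility_from_profile <- function(profile, pos1_nm, pos2_nm) {
    at <- function(p) approx(profile$position_nm, profile$intensity,
                             xout = p, rule = 2)$y
    visibility(at(pos1_nm), at(pos2_nm), at((pos1_nm + pos2_nm) / 2))
}

#' Smallest Sparrow-resolved separation of a diverging-line image
#'
#' Scans a reconstruction (or diffraction-limited image) of the diverging
#' two-line structure along the divergence axis: rows are grouped into
#' axial windows, each window's transverse profile (column means over the
#' window) is tested with the Sparrow criterion, and the smallest
#' separation at which the lines remain resolved is located by walking
#' from the widest separation towards zero until the dip disappears.
#' A window only counts as resolved when the two detected maxima bracket
#' the structure axis and lie within `position_tol_nm` of the known
#' filament positions.
#'
#' @param img an `srrf_image`, [image_stack()] frame, or matrix.
#' @param pixel_size_nm pixel size of `img` (taken from an `srrf_image`
#'   automatically).
#' @param geometry geometry list of [make_diverging_lines()] (fields
#'   `length_nm`, `max_separation_nm`, `center_x_nm`).
#' @param origin_nm image origin `c(x0, y0)` in the geometry frame (the
#'   rendered stack stores it as `metadata$fov`).
#' @param axial_window_nm axial averaging window (default 300 nm).
#' @param min_dip_fraction Sparrow dip threshold (default 0.01).
#' @param position_tol_nm tolerance on detected peak positions relative
#'   to the true filament positions (default 150 nm).
#' @return list with `separation_nm`/`resolved` per window (widest first)
#'   and `smallest_resolved_nm`.
#' @export
scan_diverging_separation <- function(img, pixel_size_nm = NA, geometry,
                                      origin_nm = c(0, 0),
                                      axial_window_nm = 300,
                                      min_dip_fraction = 0.01,
                                      position_tol_nm = 150) {
    if (is.list(img) && !is.null(img$values)) {
        if (is.na(pixel_size_nm)) pixel_size_nm <- img$pixel_size_nm
        img <- img$values
    }
    px <- pixel_size_nm
    ycent <- (seq_len(nrow(img)) - 0.5) * px + origin_nm[2L]
    xcent <- (seq_len(ncol(img)) - 0.5) * px + origin_nm[1L]
    sep_at <- function(y) geometry$max_separation_nm *
        pmin(pmax(y / geometry$length_nm, 0), 1)
    cx <- geometry$center_x_nm
    inside <- ycent >= 0 & ycent <= geometry$length_nm
    ymin <- min(ycent[inside]); ymax <- max(ycent[inside])
    edges <- seq(ymax, ymin, by = -axial_window_nm)
    if (length(edges) < 2L) .invalid("image spans less than one axial window")
    seps <- numeric(0); flags <- logical(0)
    for (w in seq_len(length(edges) - 1L)) {
        rows <- which(ycent <= edges[w] & ycent > edges[w + 1L])
        if (length(rows) == 0L) next
        ymid <- (edges[w] + edges[w + 1L]) / 2
        sep <- sep_at(ymid)
        cols <- which(abs(xcent - cx) <=
                      geometry$max_separation_nm / 2 + 2.5 * position_tol_nm)
        prof <- data.frame(position_nm = xcent[cols],
                           intensity = colMeans(img[rows, cols, drop = FALSE]))
        sp <- sparrow_resolved(prof, min_dip_fraction)
        ok <- sp$resolved
        if (ok) {
            expected <- cx + c(-1, 1) * sep / 2
            ok <- sp$peaks_nm[1L] < cx && sp$peaks_nm[2L] > cx &&
                all(abs(sort(sp$peaks_nm) - expected) <= position_tol_nm)
        }
        seps <- c(seps, sep); flags <- c(flags, ok)
    }
    smallest <- NA_real_
    for (i in seq_along(seps)) {
        if (!flags[i]) break
        smallest <- seps[i]
    }
    list(separation_nm = seps, resolved = flags,
         smallest_resolved_nm = smallest)
}
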