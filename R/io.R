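#' Read a multi-page TIFF into an image stack
#'
#' Pages are read in file order; 8/16-bit unsigned pages come back as the
#' stored integer sample values.  32-bit float stacks written by
#' [write_stack()] are restored through their sidecar scaling file.
#' Pixel size and frame interval are always supplied by the caller
#' (configuration metadata), never trusted from TIFF tags.
#'
#' @param path TIFF file path.
#' @param pixel_size_nm pixel size in nm.
#' @param frame_interval_s frame interval in seconds (default 1).
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size_nm, frame_interval_s = 1) {
    if (!file.exists(path)) .invalid("file not found: %s", path)
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    for (i in seq_along(pages)) {
        if (length(dim(pages[[i]])) != 2L)
            .invalid("page %d is not single-channel grayscale", i)
        if (i > 1L && !identical(dim(pages[[i]]), dim(pages[[1L]])))
            .invalid("page %d dimensions differ from page 1", i)
    }
    side <- paste0(path, ".scale.json")
    pages <- lapply(pages, function(p) {
        bits <- attr(p, "bits.per.sample")
        v <- unclass(p)
        attributes(v) <- list(dim = dim(p))
        # integer pages come back normalized by (2^bits - 1); float pages
        # are stored as-is in [0, 1] and rescaled via the sidecar below
        if (!is.null(bits) && bits <= 16L) v <- round(v * (2^bits - 1))
        v
    })
    if (file.exists(side)) {
        sc <- jsonlite::read_json(side, simplifyVector = TRUE)
        pages <- lapply(pages, function(p) p * sc$scale + sc$offset)
    }
    image_stack(pages, pixel_size_nm, frame_interval_s)
}

#' Write an image stack or SRRF image as multi-page TIFF
#'
#' `uint16` output (simulated camera data) stores rounded sample values;
#' negative values are clipped to zero with a warning.  `float32` output
#' (reconstructions) stores the values through an affine rescaling
#' recorded in a `<path>.scale.json` sidecar so that [read_stack()]
#' restores the original range.
#'
#' @param x an [image_stack()], `srrf_image`, matrix or 3-D array.
#' @param path destination file.
#' @param dtype `"uint16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path, dtype = c("uint16", "float32")) {
    dtype <- match.arg(dtype)
    a <- if (is.list(x) && !is.null(x$frames)) x$frames
         else if (is.list(x) && !is.null(x$values)) x$values
         else x
    if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
    frames <- lapply(seq_len(dim(a)[3L]), function(t) a[, , t])
    if (dtype == "uint16") {
        if (any(vapply(frames, min, 0) < 0))
            warning("negative values clipped to 0 for unsigned output")
        frames <- lapply(frames, function(m)
            pmin(pmax(round(m), 0), 65535) / 65535)
        tiff::writeTIFF(frames, path, bits.per.sample = 16L)
    } else {
        lo <- min(vapply(frames, min, 0))
        hi <- max(vapply(frames, max, 0))
        scale <- if (hi > lo) hi - lo else 1
        frames <- lapply(frames, function(m) (m - lo) / scale)
        tiff::writeTIFF(frames, path, bits.per.sample = 32L)
        jsonlite::write_json(list(offset = lo, scale = scale),
                             paste0(path, ".scale.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    invisible(path)
}

#' Write ground truth tables of a simulated movie
#'
#' Emits `<prefix>_emitters.csv` (emitter id, x_nm, y_nm) and
#' `<prefix>_on_fractions.csv` (per-emitter per-frame on-fractions).
#'
#' @param movie a `ground_truth_movie` from [simulate_movie()].
#' @param prefix output path prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_ground_truth <- function(movie, prefix) {
    p1 <- paste0(prefix, "_emitters.csv")
    p2 <- paste0(prefix, "_on_fractions.csv")
    df <- data.frame(id = seq_len(nrow(movie$field$positions)),
                     x_nm = movie$field$positions[, 1L],
                     y_nm = movie$field$positions[, 2L])
    write.csv(df, p1, row.names = FALSE)
    write.csv(as.data.frame(movie$on_fractions), p2, row.names = FALSE)
    invisible(c(p1, p2))
}
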