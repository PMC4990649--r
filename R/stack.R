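#' Time-ordered fluorescence image stack
#'
#' Container for a sequence of 2-D intensity frames sharing one pixel size
#' and frame interval.  Frames are stored as an `H x W x T` numeric array
#' (rows are y, columns are x, arbitrary intensity units).
#'
#' @param frames numeric matrix (single frame), 3-D array, or list of
#'   equally sized matrices.
#' @param pixel_size_nm positive pixel pitch in nanometres.
#' @param frame_interval_s positive frame interval in seconds.
#' @param metadata free-form named list of annotations.
#' @return An object of class `image_stack` with elements `frames`
#'   (3-D array), `pixel_size_nm`, `frame_interval_s` and `metadata`.
#' @export
image_stack <- function(frames, pixel_size_nm, frame_interval_s = 1,
                        metadata = list()) {
    if (is.list(frames) && !is.array(frames)) {
        dims <- unique(lapply(frames, dim))
        if (length(dims) != 1L)
            .invalid("all frames must share identical dimensions")
        frames <- array(unlist(frames, use.names = FALSE),
                        dim = c(dims[[1L]], length(frames)))
    }
    if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
    if (!is.array(frames) || length(dim(frames)) != 3L)
        .invalid("frames must be a matrix, 3-D array or list of matrices")
    if (dim(frames)[3L] < 1L) .invalid("frame count must be >= 1")
    if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0)
        .invalid("pixel_size_nm must be positive")
    if (!is.numeric(frame_interval_s) || frame_interval_s <= 0)
        .invalid("frame_interval_s must be positive")
    structure(list(frames = frames,
                   pixel_size_nm = as.numeric(pixel_size_nm),
                   frame_interval_s = as.numeric(frame_interval_s),
                   metadata = metadata),
              class = "image_stack")
}

#' Number of frames in a stack
#' @param x an `image_stack`.
#' @return integer frame count.
#' @export
n_frames <- function(x) dim(x$frames)[3L]

#' Extract one frame as a matrix
#' @param x an `image_stack`.
#' @param t frame index (1-based).
#' @return numeric matrix.
#' @export
get_frame <- function(x, t) x$frames[, , t, drop = TRUE]

#' @export
print.image_stack <- function(x, ...) {
    d <- dim(x$frames)
    cat(sprintf("image_stack: %d frame(s) of %d x %d px, %.4g nm/px, %.4g s/frame\n",
                d[3L], d[1L], d[2L], x$pixel_size_nm, x$frame_interval_s))
    invisible(x)
}

#' @export
print.srrf_image <- function(x, ...) {
    d <- dim(x$values)
    cat(sprintf("srrf_image: %d x %d px, %.4g nm/px (method: %s)\n",
                d[1L], d[2L], x$pixel_size_nm,
                if (is.null(x$provenance$temporal$method)) "?"
                else x$provenance$temporal$method))
    invisible(x)
}
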