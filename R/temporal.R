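#' Temporal collapse settings
#'
#' How a stack of per-frame radiality maps is collapsed into a single
#' super-resolution image: pixel-wise temporal `mean`, pairwise temporal
#' auto-correlation at a fixed frame lag (`pairwise_correlation`; lag 0 is
#' the temporal variance), or a higher-order temporal auto-cumulant at
#' zero lag (`cumulant`, orders 2-4, SOFI-style).  The default is the
#' pairwise correlation at lag 0, which suppresses temporally uncorrelated
#' noise-induced radiality peaks.
#'
#' @param method one of `"mean"`, `"pairwise_correlation"`, `"cumulant"`.
#' @param order cumulant order (2, 3 or 4); only with `method = "cumulant"`.
#' @param lag_frames non-negative integer frame lag; only with
#'   `method = "pairwise_correlation"`.
#' @return A list of class `temporal_settings`.
#' @export
temporal_settings <- function(method = c("pairwise_correlation", "mean",
                                         "cumulant"),
                              order = 2L, lag_frames = 0L) {
    method <- match.arg(method)
    if (method == "cumulant" && !order %in% 2:4)
        .invalid("cumulant order must be 2, 3 or 4")
    if (method == "pairwise_correlation" && lag_frames < 0L)
        .invalid("lag_frames must be non-negative")
    structure(list(method = method, order = as.integer(order),
                   lag_frames = as.integer(lag_frames)),
              class = "temporal_settings")
}

.stack_array <- function(stack) {
    if (is.list(stack) && !is.null(stack$values)) stack$values
    else if (is.array(stack) && length(dim(stack)) == 3L) stack
    else if (is.matrix(stack)) array(stack, dim = c(dim(stack), 1L))
    else .invalid("expected a 3-D array or radiality stack")
}

.as_srrf_image <- function(values, pixel_size_nm = NA_real_,
                           provenance = list()) {
    structure(list(values = values, pixel_size_nm = pixel_size_nm,
                   provenance = provenance),
              class = "srrf_image")
}

#' Pixel-wise temporal mean of a radiality stack
#'
#' @param stack 3-D array (`H x W x T`) or object with a `values` array.
#' @param pixel_size_nm optional pixel size carried to the output.
#' @return An `srrf_image`.
#' @export
temporal_mean <- function(stack, pixel_size_nm = NA_real_) {
    a <- .stack_array(stack)
    .as_srrf_image(rowMeans(a, dims = 2L), pixel_size_nm,
                   list(temporal = list(method = "mean")))
}

#' Pixel-wise pairwise temporal auto-correlation
#'
#' For each pixel, the mean over `t` of
#' `(R_t - mean(R)) * (R_{t+lag} - mean(R))` with the temporal mean taken
#' over the full stack; `lag = 0` gives the population temporal variance.
#' Radiality fluctuations that are uncorrelated in time (noise-induced
#' peaks) average towards zero as the number of frames grows.
#'
#' @param stack 3-D array (`H x W x T`).
#' @param lag non-negative integer frame lag, strictly less than `T`.
#' @param pixel_size_nm optional pixel size carried to the output.
#' @return An `srrf_image`.
#' @export
temporal_pairwise_correlation <- function(stack, lag = 0L,
                                          pixel_size_nm = NA_real_) {
    a <- .stack_array(stack)
    tt <- dim(a)[3L]
    if (lag < 0L || lag >= tt) .invalid("lag must satisfy 0 <= lag < n frames")
    mu <- rowMeans(a, dims = 2L)
    n <- tt - lag
    acc <- 0
    for (t in seq_len(n))
        acc <- acc + (a[, , t] - mu) * (a[, , t + lag] - mu)
    .as_srrf_image(acc / n, pixel_size_nm,
                   list(temporal = list(method = "pairwise_correlation",
                                        lag_frames = lag)))
}

#' Pixel-wise temporal auto-cumulant at zero lag
#'
#' Central auto-cumulants with population (1/T) normalization:
#' `k2 = m2`, `k3 = m3`, `k4 = m4 - 3 * m2^2` with `m_n` the n-th central
#' temporal moment.  Cumulants above order 2 vanish for Gaussian noise,
#' which is what makes them useful for contrast enhancement.
#'
#' @param stack 3-D array (`H x W x T`).
#' @param order cumulant order: 2, 3 or 4.
#' @param pixel_size_nm optional pixel size carried to the output.
#' @return An `srrf_image`.
#' @export
temporal_cumulant <- function(stack, order = 2L, pixel_size_nm = NA_real_) {
    a <- .stack_array(stack)
    if (!order %in% 2:4) .invalid("order must be 2, 3 or 4")
    tt <- dim(a)[3L]
    if (tt < order) .invalid("stack must contain at least `order` frames")
    mu <- rowMeans(a, dims = 2L)
    m2 <- m3 <- m4 <- 0
    for (t in seq_len(tt)) {
        d <- a[, , t] - mu
        d2 <- d * d
        m2 <- m2 + d2
        if (order >= 3L) m3 <- m3 + d2 * d
        if (order == 4L) m4 <- m4 + d2 * d2
    }
    m2 <- m2 / tt
    v <- switch(as.character(order),
                "2" = m2,
                "3" = m3 / tt,
                "4" = m4 / tt - 3 * m2 * m2)
    .as_srrf_image(v, pixel_size_nm,
                   list(temporal = list(method = "cumulant", order = order)))
}

#' Full frame-stack to SRRF image reconstruction
#'
#' Applies the radiality transform and the configured weighting to every
#' frame of the stack, then collapses the radiality time series pixel by
#' pixel with the selected temporal statistic.  Frames are processed in a
#' streaming fashion (only running sums and, for lagged correlation, a
#' short frame buffer are kept), so arbitrarily long stacks fit in memory.
#' The result is deterministic given the inputs.
#'
#' @param stack an [image_stack()].
#' @param rset [radiality_settings()].
#' @param tset [temporal_settings()].
#' @return An `srrf_image` whose pixel size is the stack pixel size
#'   divided by the magnification.
#' @export
srrf_reconstruct <- function(stack, rset = radiality_settings(),
                             tset = temporal_settings()) {
    tt <- n_frames(stack)
    lag <- if (tset$method == "pairwise_correlation") tset$lag_frames else 0L
    if (tset$method == "pairwise_correlation" && lag >= tt)
        .invalid("lag_frames must be smaller than the stack length")
    if (tset$method == "cumulant" && tt < tset$order)
        .invalid("stack shorter than the cumulant order")
    s1 <- s2 <- s3 <- s4 <- cc <- aa <- bb <- 0
    buf <- vector("list", max(lag, 0L))
    need34 <- tset$method == "cumulant" && tset$order >= 3L
    for (t in seq_len(tt)) {
        fr <- get_frame(stack, t)
        v <- tryCatch({
            g <- compute_gradient(fr)
            raw <- radiality_map_from_gradient(g$gx, g$gy, rset,
                                               stack$pixel_size_nm)
            weight_radiality(raw, fr, g, rset)$values
        }, error = function(e)
            stop(sprintf("frame %d: %s", t, conditionMessage(e)), call. = FALSE))
        s1 <- s1 + v
        if (tset$method != "mean") s2 <- s2 + v * v
        if (need34) { s3 <- s3 + v^3; s4 <- s4 + v^4 }
        if (tset$method == "pairwise_correlation" && lag > 0L) {
            if (t > lag) {
                prev <- buf[[(t - lag - 1L) %% lag + 1L]]
                cc <- cc + prev * v
                aa <- aa + prev
                bb <- bb + v
            }
            buf[[(t - 1L) %% lag + 1L]] <- v
        }
    }
    mu <- s1 / tt
    px <- stack$pixel_size_nm / rset$magnification
    vals <- switch(tset$method,
        mean = mu,
        pairwise_correlation = {
            if (lag == 0L) s2 / tt - mu * mu
            else {
                n <- tt - lag
                (cc - mu * aa - mu * bb + n * mu * mu) / n
            }
        },
        cumulant = {
            m2 <- s2 / tt - mu^2
            switch(as.character(tset$order),
                   "2" = m2,
                   "3" = s3 / tt - 3 * mu * (s2 / tt) + 2 * mu^3,
                   "4" = {
                       m4 <- s4 / tt - 4 * mu * (s3 / tt) +
                           6 * mu^2 * (s2 / tt) - 3 * mu^4
                       m4 - 3 * m2 * m2
                   })
        })
    .as_srrf_image(vals, px,
                   list(temporal = unclass(tset), radiality = unclass(rset),
                        n_frames = tt, source = stack$metadata))
}
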