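#' Wavelet analysis settings
#'
#' Configuration of the spatial-complexity metric: each activity frame is
#' padded to the next dyadic square, decomposed with the non-standard
#' (quad-tree) two-dimensional Haar wavelet transform, and the number of
#' coefficients larger than `threshold` in absolute value is the per-frame
#' complexity C(t).
#'
#' @param threshold coefficient magnitude threshold (`th`); the study
#'   protocol uses 1.
#' @param pad padding mode to reach a dyadic square: `"symmetric"`
#'   (half-sample reflection, the default, avoiding artificial edges),
#'   `"zero"`, or `"periodic"`.
#' @param orthonormal use the orthonormal (1/sqrt(2)) Haar filters; when
#'   `FALSE` the unnormalized average/difference pair is used.
#' @param count_scaling include the coarsest scaling coefficient in the
#'   count.
#' @return An object of class `io_wavelet_config`.
#' @export
wavelet_config <- function(threshold = 1,
                           pad = c("symmetric", "zero", "periodic"),
                           orthonormal = TRUE, count_scaling = TRUE) {
  if (threshold < 0) stop("'threshold' must be >= 0")
  structure(list(threshold = threshold, pad = match.arg(pad),
                 orthonormal = orthonormal,
                 count_scaling = count_scaling),
            class = "io_wavelet_config")
}

#' Pad a frame to the next dyadic square
#'
#' @param frame numeric matrix.
#' @param mode `"symmetric"` (half-sample reflection), `"zero"` or
#'   `"periodic"`.
#' @return A `side x side` matrix with `side` the smallest power of two not
#'   below either frame dimension.
#' @export
pad_dyadic <- function(frame, mode = "symmetric") {
  side <- 2^ceiling(log2(max(dim(frame))))
  .pad_axis <- function(n, extra) {
    base <- seq_len(n)
    if (extra == 0) return(base)
    switch(mode,
           symmetric = {
             refl <- integer(0)
             while (length(refl) < extra)
               refl <- c(refl, rev(base), base)
             c(base, refl[seq_len(extra)])
           },
           periodic = c(base, rep_len(base, extra)),
           zero = c(base, rep(NA_integer_, extra)))
  }
  ri <- .pad_axis(nrow(frame), side - nrow(frame))
  ci <- .pad_axis(ncol(frame), side - ncol(frame))
  out <- frame[ifelse(is.na(ri), 1, ri), ifelse(is.na(ci), 1, ci)]
  if (mode == "zero") {
    out[is.na(ri), ] <- 0
    out[, is.na(ci)] <- 0
  }
  out
}

#' Non-standard 2D Haar wavelet transform
#'
#' Applies the full quad-tree (non-standard) Haar decomposition: at each
#' resolution level the current low-pass block is filtered along rows and
#' then along columns, the three detail quadrants are stored, and the
#' transform recurses on the low-low quadrant down to a single scaling
#' coefficient. The transform is orthonormal (Parseval holds) and exactly
#' invertible via [haar2d_inverse()].
#'
#' @param frame numeric matrix (any size; padded per `config`).
#' @param config an [wavelet_config()] object.
#' @return A `side x side` coefficient matrix in pyramid layout, with the
#'   coarsest scaling coefficient at `[1, 1]` and attribute `"side"`.
#' @examples
#' haar2d_nonstandard(matrix(1, 2, 2)) # coefficients 2, 0, 0, 0
#' @export
haar2d_nonstandard <- function(frame, config = wavelet_config()) {
  frame <- as.matrix(frame)
  if (length(frame) == 0) stop("empty frame")
  if (any(!is.finite(frame))) stop("frame must be finite")
  x <- pad_dyadic(frame, config$pad)
  side <- nrow(x)
  w <- if (config$orthonormal) 1 / sqrt(2) else 0.5
  s <- side
  while (s > 1) {
    half <- s / 2
    odd <- seq(1, s, by = 2)
    even <- odd + 1
    blk <- x[seq_len(s), seq_len(s), drop = FALSE]
    # rows
    lo <- (blk[, odd, drop = FALSE] + blk[, even, drop = FALSE]) * w
    hi <- (blk[, odd, drop = FALSE] - blk[, even, drop = FALSE]) * w
    blk <- cbind(lo, hi)
    # columns
    lo <- (blk[odd, , drop = FALSE] + blk[even, , drop = FALSE]) * w
    hi <- (blk[odd, , drop = FALSE] - blk[even, , drop = FALSE]) * w
    x[seq_len(s), seq_len(s)] <- rbind(lo, hi)
    s <- half
  }
  attr(x, "side") <- side
  attr(x, "orthonormal") <- config$orthonormal
  x
}

#' Inverse of the non-standard 2D Haar transform
#'
#' @param coefs coefficient matrix from [haar2d_nonstandard()].
#' @return The reconstructed padded frame.
#' @export
haar2d_inverse <- function(coefs) {
  x <- as.matrix(coefs)
  side <- nrow(x)
  ortho <- attr(coefs, "orthonormal")
  if (is.null(ortho)) ortho <- TRUE
  s <- 2
  while (s <= side) {
    half <- s / 2
    odd <- seq(1, s, by = 2)
    even <- odd + 1
    blk <- x[seq_len(s), seq_len(s), drop = FALSE]
    lo <- blk[seq_len(half), , drop = FALSE]
    hi <- blk[half + seq_len(half), , drop = FALSE]
    out <- matrix(0, s, s)
    if (ortho) {
      out[odd, ] <- (lo + hi) / sqrt(2)
      out[even, ] <- (lo - hi) / sqrt(2)
    } else {
      out[odd, ] <- lo + hi
      out[even, ] <- lo - hi
    }
    lo <- out[, seq_len(half), drop = FALSE]
    hi <- out[, half + seq_len(half), drop = FALSE]
    if (ortho) {
      out[, odd] <- (lo + hi) / sqrt(2)
      out[, even] <- (lo - hi) / sqrt(2)
    } else {
      out[, odd] <- lo + hi
      out[, even] <- lo - hi
    }
    x[seq_len(s), seq_len(s)] <- out
    s <- 2 * s
  }
  attr(x, "side") <- NULL
  attr(x, "orthonormal") <- NULL
  x
}

#' Count supra-threshold wavelet coefficients
#'
#' @param coefs coefficient matrix from [haar2d_nonstandard()].
#' @param threshold magnitude threshold (strictly exceeded).
#' @param count_scaling include the coarsest scaling coefficient at `[1, 1]`.
#' @return Nonnegative integer count.
#' @export
complexity_count <- function(coefs, threshold = 1, count_scaling = TRUE) {
  n <- sum(abs(coefs) > threshold)
  if (!count_scaling && abs(coefs[1, 1]) > threshold) n <- n - 1L
  as.integer(n)
}

#' Spatial complexity series C(t)
#'
#' Per-frame count of non-standard 2D Haar coefficients exceeding the
#' threshold in absolute value. Low values indicate spatially coherent
#' (synchronized) activity; high values indicate complex spatial structure.
#'
#' @param frames a `time x rows x cols` array (e.g. `record$frames`), an
#'   [simulate_network()] record, or a list of matrices.
#' @param config an [wavelet_config()] object.
#' @param times optional frame times (ms); taken from the record if
#'   available.
#' @return An object of class `io_complexity`: data.frame with columns `t`
#'   (ms) and `C` (coefficient counts).
#' @export
complexity_series <- function(frames, config = wavelet_config(),
                              times = NULL) {
  if (inherits(frames, "io_record")) {
    if (is.null(times)) times <- frames$times
    frames <- frames$frames
  }
  getf <- if (is.list(frames)) {
    nT <- length(frames)
    function(i) frames[[i]]
  } else {
    nT <- dim(frames)[1]
    function(i) frames[i, , ]
  }
  if (is.null(times)) times <- seq_len(nT) - 1
  C <- integer(nT)
  for (i in seq_len(nT))
    C[i] <- complexity_count(haar2d_nonstandard(getf(i), config),
                             config$threshold, config$count_scaling)
  structure(data.frame(t = times, C = C),
            class = c("io_complexity", "data.frame"))
}

#' @export
plot.io_complexity <- function(x, ...) {
  graphics::plot(x$t, x$C, type = "l", xlab = "time (ms)",
                 ylab = "C(t) (supra-threshold DWT coefficients)", ...)
  invisible(x)
}
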