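#' Binarize an activity frame at the firing threshold
#'
#' A cell is marked 1 when its membrane potential strictly exceeds the
#' firing threshold (around -47 mV in this model), 0 otherwise.
#'
#' @param frame numeric matrix or `time x rows x cols` array of membrane
#'   potentials (mV).
#' @param threshold firing threshold (mV).
#' @return Logical object of the same shape.
#' @export
binarize <- function(frame, threshold = -47) {
  frame > threshold
}

#' Circle through three points
#'
#' Solves `x^2 + y^2 + A x + B y + C = 0` through the three points by the
#' 3 x 3 linear system; the center is `-(A, B) / 2` and the radius
#' `sqrt(A^2/4 + B^2/4 - C)`. Nearly collinear triples (system determinant
#' below 1e-12) are reported via the `collinear` flag rather than an error.
#'
#' @param p1,p2,p3 numeric length-2 points `(row, col)` (any planar
#'   coordinates).
#' @return A list with `center` (length-2), `radius`, and logical
#'   `collinear`; `center` and `radius` are `NA` for collinear input.
#' @examples
#' circle_through_points(c(0, 1), c(1, 0), c(0, -1)) # unit circle at origin
#' @export
circle_through_points <- function(p1, p2, p3) {
  P <- rbind(p1, p2, p3)
  M <- cbind(P, 1)
  D <- det(M)
  if (abs(D) < 1e-12)
    return(list(center = c(NA_real_, NA_real_), radius = NA_real_,
                collinear = TRUE))
  b <- -(P[, 1]^2 + P[, 2]^2)
  abc <- solve(M, b)
  center <- -abc[1:2] / 2
  radius <- sqrt(abc[1]^2 / 4 + abc[2]^2 / 4 - abc[3])
  list(center = unname(center), radius = unname(radius), collinear = FALSE)
}

#' Rasterize a circle as a one-pixel-wide mask
#'
#' Midpoint-style scan along both axes producing an 8-connected ring of
#' pixels, clipped to the frame.
#'
#' @param center continuous center `c(row, col)`, 1-based.
#' @param radius radius in cell units.
#' @param rows,cols frame dimensions.
#' @return Integer matrix (n x 2) of pixel `(row, col)` coordinates.
#' @export
rasterize_circle <- function(center, radius, rows, cols) {
  .raster_circle_cpp(center[1], center[2], radius, rows, cols)
}

#' Detect wave-front arcs in a binary frame
#'
#' Randomized triple-sampling detector: triples of suprathreshold pixels are
#' sampled uniformly, the unique circle through each triple is fitted and
#' rasterized as a one-pixel-wide mask, and candidates are scored by their
#' support -- the fraction of mask pixels active in the frame. Passing
#' candidates are refined by a least-squares fit over their supporting
#' annulus; each detection round spends up to `max_trials` triples and
#' accepts the best-supported candidate, which then removes its supporting
#' pixels from the frame. Rounds repeat until no candidate clears the
#' support bar or fewer than three pixels remain.
#'
#' @param frame logical (binarized) matrix, or numeric matrix binarized at
#'   `threshold`.
#' @param min_support minimum fraction of mask pixels that must be active.
#' @param max_trials triple-sampling budget per detection round.
#' @param radius_range accepted radius bounds (cells), excluding degenerate
#'   three-pixel fits and frame-sized circles.
#' @param threshold binarization threshold used when `frame` is numeric.
#' @param min_hits minimum number of active mask pixels for an accepted arc,
#'   guarding against chance alignments of isolated pixels.
#' @param remove_band accepted arcs consume the pixels within this distance
#'   of the fitted circle (cells), so rasterization round-off cannot strand
#'   ring fragments that would re-detect as spurious arcs.
#' @param seed optional RNG seed (same seed, same arc list).
#' @return A data.frame of arcs: `center_row`, `center_col`, `radius`,
#'   `support`, `n_hit`, `n_mask`, with the supporting pixel sets in
#'   attribute `"pixels"`.
#' @export
detect_arcs <- function(frame, min_support = 0.25, max_trials = 2000,
                        radius_range = c(2, 30), threshold = -47,
                        min_hits = 8, remove_band = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.logical(frame)) frame <- binarize(frame, threshold)
  if (min_support <= 0 || min_support > 1)
    stop("'min_support' must lie in (0, 1]")
  res <- .detect_arcs_cpp(frame, min_support, as.integer(max_trials),
                          radius_range[1], radius_range[2],
                          as.integer(min_hits), remove_band)
  out <- data.frame(center_row = res$center_row,
                    center_col = res$center_col,
                    radius = res$radius, support = res$support,
                    n_hit = res$n_hit, n_mask = res$n_mask)
  attr(out, "pixels") <- res$pixels
  out
}

#' Detect arcs across a frame stack
#'
#' Runs [detect_arcs()] on every `stride`-th frame of a record or array and
#' concatenates the results with frame indices and times.
#'
#' @param frames an [simulate_network()] record or `time x rows x cols`
#'   array of membrane potentials (mV); logical arrays are used as-is.
#' @param threshold binarization threshold (mV).
#' @param stride analyze every `stride`-th frame.
#' @param times frame times (ms); taken from the record if available.
#' @param seed RNG seed for the whole stack.
#' @param ... passed to [detect_arcs()].
#' @return A data.frame of arcs with `frame` (index into the stack) and
#'   `time` columns.
#' @export
detect_arcs_stack <- function(frames, threshold = -47, stride = 1,
                              times = NULL, seed = NULL, ...) {
  if (inherits(frames, "io_record")) {
    if (is.null(times)) times <- frames$times
    frames <- frames$frames
  }
  nT <- dim(frames)[1]
  if (is.null(times)) times <- seq_len(nT) - 1
  if (!is.null(seed)) set.seed(seed)
  sel <- seq(1, nT, by = stride)
  out <- vector("list", length(sel))
  for (i in seq_along(sel)) {
    fr <- frames[sel[i], , ]
    a <- detect_arcs(if (is.logical(fr)) fr else binarize(fr, threshold),
                     ...)
    if (nrow(a)) {
      a$frame <- sel[i]
      a$time <- times[sel[i]]
      attr(a, "pixels") <- NULL
      out[[i]] <- a
    }
  }
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Track arcs across frames
#'
#' Greedy nearest-center linking: arcs in successive analyzed frames are
#' joined to the track whose last center is closest, within
#' `center_tol` cells and at most `max_gap` analyzed frames back, and whose
#' radius is continuous (change at most `radius_tol` cells per link) --
#' thick fronts can yield concentric arcs in one frame, and the radius
#' constraint keeps them from cross-linking. Tracks shorter than `min_len`
#' arcs are discarded.
#'
#' @param arcs data.frame from [detect_arcs_stack()] (must be ordered by
#'   frame; unordered input is an error).
#' @param center_tol maximum center displacement between linked arcs (cells).
#' @param radius_tol maximum radius change between linked arcs (cells).
#' @param max_gap maximum gap in analyzed frames between linked arcs.
#' @param min_len minimum number of arcs per retained track.
#' @param min_duration optional minimum track duration (ms, needs a `time`
#'   column); unlike `min_len` this filter is independent of the analysis
#'   cadence, so fragments of a front that surface for a couple of frames do
#'   not count as tracks at fine strides.
#' @return The arcs data.frame with a `track_id` column, tracks of length
#'   below `min_len` (or duration below `min_duration`) removed; ordered by
#'   track and frame.
#' @export
track_arcs <- function(arcs, center_tol = 5, radius_tol = 5, max_gap = 2,
                       min_len = 3, min_duration = NULL) {
  if (is.null(arcs) || !nrow(arcs)) {
    if (!is.null(arcs)) arcs$track_id <- integer(0)
    return(arcs)
  }
  if (is.unsorted(arcs$frame))
    stop("'arcs' must be ordered by frame (unordered input)")
  fr_levels <- sort(unique(arcs$frame))
  fr_pos <- match(arcs$frame, fr_levels)
  # analyzed-frame spacing: gaps are measured in actual frame distance, not
  # in positions within the (possibly sparse) list of frames carrying arcs
  fr_step <- if (length(fr_levels) > 1) min(diff(fr_levels)) else 1
  arcs$track_id <- NA_integer_
  # active track bookkeeping
  last_row <- numeric(0)
  last_col <- numeric(0)
  last_rad <- numeric(0)
  last_pos <- numeric(0)
  track_of <- integer(0)
  n_tracks <- 0L
  for (p in seq_along(fr_levels)) {
    fnow <- fr_levels[p]
    idx <- which(fr_pos == p)
    alive <- which(fnow - last_pos <= max_gap * fr_step &
                     fnow - last_pos >= 1)
    taken <- rep(FALSE, length(alive))
    for (j in idx) {
      if (length(alive)) {
        d <- sqrt((last_row[alive] - arcs$center_row[j])^2 +
                    (last_col[alive] - arcs$center_col[j])^2)
        dr <- abs(last_rad[alive] - arcs$radius[j])
        cost <- d + dr
        cost[taken | d > center_tol | dr > radius_tol] <- Inf
        best <- which.min(cost)
        if (length(best) && is.finite(cost[best])) {
          tid <- track_of[alive[best]]
          arcs$track_id[j] <- tid
          taken[best] <- TRUE
          last_row[alive[best]] <- arcs$center_row[j]
          last_col[alive[best]] <- arcs$center_col[j]
          last_rad[alive[best]] <- arcs$radius[j]
          last_pos[alive[best]] <- fnow
          next
        }
      }
      n_tracks <- n_tracks + 1L
      arcs$track_id[j] <- n_tracks
      last_row <- c(last_row, arcs$center_row[j])
      last_col <- c(last_col, arcs$center_col[j])
      last_rad <- c(last_rad, arcs$radius[j])
      last_pos <- c(last_pos, fnow)
      track_of <- c(track_of, n_tracks)
      alive <- which(fnow - last_pos <= max_gap * fr_step &
                       fnow - last_pos >= 1)
      taken <- rep(FALSE, length(alive))
    }
  }
  keep <- table(arcs$track_id)
  arcs <- arcs[arcs$track_id %in% as.integer(names(keep)[keep >= min_len]), ]
  if (!is.null(min_duration) && nrow(arcs) && !is.null(arcs$time)) {
    dur <- tapply(arcs$time, arcs$track_id, function(x) diff(range(x)))
    ok <- as.integer(names(dur)[dur >= min_duration])
    arcs <- arcs[arcs$track_id %in% ok, ]
  }
  arcs[order(arcs$track_id, arcs$frame), ]
}

# squared wrapped/unwrapped distance from points to a cluster's rectangle
.cluster_center <- function(topology, cl) {
  c(cl$origin[1] + (cl$height - 1) / 2, cl$origin[2] + (cl$width - 1) / 2)
}

.in_cluster <- function(row, col, cl, margin = 0) {
  row >= cl$origin[1] - margin & row <= cl$origin[1] + cl$height - 1 + margin &
    col >= cl$origin[2] - margin & col <= cl$origin[2] + cl$width - 1 + margin
}

#' Classify tracked arcs into sources and sinks and report radii
#'
#' A track is source-type when the least-squares slope of radius versus time
#' is positive (the wave front expands) and sink-type when negative.
#' Expanding tracks are attributed to the cluster containing (or nearest to,
#' within `margin` cells of) their mean center; shrinking tracks to the
#' cluster nearest their final center. Radii are sampled every
#' `sample_interval` ms: for sources at offsets t1, t2, ... from track
#' birth; for sinks aligned so that the last offset (t5 by default)
#' coincides with track termination.
#'
#' @param tracks data.frame from [track_arcs()] (needs `time`, `radius`,
#'   `center_row`, `center_col`, `track_id`).
#' @param clusters named list of [cluster_spec()] objects (e.g.
#'   `list(source = ..., sink = ...)`).
#' @param topology the lattice the tracks were observed on.
#' @param sample_interval radius sampling interval (ms).
#' @param n_offsets number of sample offsets (columns t1..t5).
#' @param margin attribution margin around a cluster (cells) for expanding
#'   tracks.
#' @return An object of class `io_sourcesink`: per-track table, the
#'   radius-at-offset report (mean, sd, n per cluster role and offset) and
#'   attribution fractions (`frac_expanding_at_source`: fraction of
#'   expanding tracks centered in each cluster; `frac_shrinking_at_sink`:
#'   fraction of shrinking tracks terminating nearest each cluster).
#' @export
classify_and_report <- function(tracks, clusters, topology,
                                sample_interval = 10, n_offsets = 5,
                                margin = 3) {
  if (sample_interval <= 0) stop("'sample_interval' must be > 0")
  empty <- structure(list(tracks = data.frame(), report = data.frame(),
                          attribution = data.frame(),
                          sample_interval = sample_interval),
                     class = "io_sourcesink")
  if (is.null(tracks) || !nrow(tracks)) return(empty)
  if (is.null(names(clusters)) || any(names(clusters) == ""))
    names(clusters) <- paste0("cluster", seq_along(clusters))

  ids <- unique(tracks$track_id)
  per <- data.frame(track_id = ids, class = NA_character_,
                    cluster = NA_character_, slope = NA_real_,
                    birth = NA_real_, death = NA_real_,
                    mean_row = NA_real_, mean_col = NA_real_,
                    final_row = NA_real_, final_col = NA_real_)
  centers <- lapply(clusters, .cluster_center, topology = topology)
  for (i in seq_along(ids)) {
    tr <- tracks[tracks$track_id == ids[i], ]
    tr <- tr[order(tr$time), ]
    sl <- stats::cov(tr$time, tr$radius) / stats::var(tr$time)
    per$slope[i] <- sl
    per$class[i] <- if (sl > 0) "source" else if (sl < 0) "sink"
                    else "indeterminate"
    per$birth[i] <- tr$time[1]
    per$death[i] <- tr$time[nrow(tr)]
    per$mean_row[i] <- mean(tr$center_row)
    per$mean_col[i] <- mean(tr$center_col)
    per$final_row[i] <- tr$center_row[nrow(tr)]
    per$final_col[i] <- tr$center_col[nrow(tr)]
    if (per$class[i] == "source") {
      inside <- vapply(clusters, function(cl)
        .in_cluster(per$mean_row[i], per$mean_col[i], cl, 0), TRUE)
      near <- vapply(clusters, function(cl)
        .in_cluster(per$mean_row[i], per$mean_col[i], cl, margin), TRUE)
      if (any(inside)) per$cluster[i] <- names(clusters)[which(inside)[1]]
      else if (any(near)) per$cluster[i] <- names(clusters)[which(near)[1]]
    } else if (per$class[i] == "sink") {
      d <- vapply(centers, function(ct)
        sqrt((ct[1] - per$final_row[i])^2 + (ct[2] - per$final_col[i])^2),
        0)
      per$cluster[i] <- names(clusters)[which.min(d)]
    }
  }

  # radius samples at t1..t{n_offsets}
  samp <- function(tr, targets) {
    vapply(targets, function(tt) {
      if (tt < tr$time[1] - 1e-9 || tt > tr$time[nrow(tr)] + 1e-9)
        return(NA_real_)
      j <- which.min(abs(tr$time - tt))
      if (abs(tr$time[j] - tt) <= sample_interval / 2) tr$radius[j]
      else NA_real_
    }, 0)
  }
  rad <- matrix(NA_real_, length(ids), n_offsets)
  for (i in seq_along(ids)) {
    tr <- tracks[tracks$track_id == ids[i], ]
    tr <- tr[order(tr$time), ]
    targets <- if (per$class[i] == "source")
      per$birth[i] + (seq_len(n_offsets) - 1) * sample_interval
    else
      per$death[i] - (n_offsets - seq_len(n_offsets)) * sample_interval
    rad[i, ] <- samp(tr, targets)
  }

  rep_rows <- list()
  for (cl in names(clusters)) {
    for (role in c("source", "sink")) {
      sel <- per$class == role & !is.na(per$cluster) & per$cluster == cl
      if (!any(sel)) next
      m <- rad[sel, , drop = FALSE]
      rep_rows[[length(rep_rows) + 1]] <- data.frame(
        cluster = cl, role = role,
        offset = paste0("t", seq_len(n_offsets)),
        mean_radius = colMeans(m, na.rm = TRUE),
        sd_radius = apply(m, 2, stats::sd, na.rm = TRUE),
        n = colSums(!is.na(m)))
    }
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else data.frame()

  n_exp <- sum(per$class == "source")
  n_shr <- sum(per$class == "sink")
  attribution <- data.frame(
    cluster = names(clusters),
    frac_expanding_at_source = vapply(names(clusters), function(cl)
      if (n_exp) sum(per$class == "source" & !is.na(per$cluster) &
                       per$cluster == cl) / n_exp else NA_real_, 0),
    frac_shrinking_at_sink = vapply(names(clusters), function(cl)
      if (n_shr) sum(per$class == "sink" & !is.na(per$cluster) &
                       per$cluster == cl) / n_shr else NA_real_, 0),
    row.names = NULL)

  structure(list(tracks = per, report = report, attribution = attribution,
                 radii = rad, sample_interval = sample_interval,
                 n_expanding = n_exp, n_shrinking = n_shr),
            class = "io_sourcesink")
}

#' @export
print.io_sourcesink <- function(x, ...) {
  cat("Wave-front source/sink report\n")
  if (!nrow(x$report)) {
    cat("  (no tracks)\n")
    return(invisible(x))
  }
  cat(sprintf("  %d expanding and %d shrinking tracks; radii sampled every %g ms\n",
              x$n_expanding, x$n_shrinking, x$sample_interval))
  for (cl in unique(x$report$cluster)) {
    for (role in unique(x$report$role[x$report$cluster == cl])) {
      r <- x$report[x$report$cluster == cl & x$report$role == role, ]
      vals <- ifelse(is.na(r$mean_radius) | r$n == 0, "  -  ",
                     sprintf("%.1f+-%.1f", r$mean_radius, r$sd_radius))
      cat(sprintf("  %-10s %-6s %s\n", cl, role, paste(vals, collapse = "  ")))
    }
  }
  print(x$attribution)
  invisible(x)
}
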