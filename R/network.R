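#' Periodic lattice topology of the IO network
#'
#' Builds the two-dimensional lattice of IO cells with gap-junction adjacency
#' among close neighbors. `k = 4` couples the axial (von Neumann) neighbors,
#' `k = 8` the full Moore neighborhood, and `k = 12` extends the Moore
#' neighborhood with the four axial cells at distance 2. With periodic
#' boundaries every cell has exactly `k` neighbors and border effects are
#' avoided; without them, border cells keep only in-range neighbors.
#'
#' Cells are indexed row-major and 1-based: cell `(r, c)` has index
#' `(r - 1) * cols + c`.
#'
#' @param rows,cols lattice dimensions (each at least 3).
#' @param k neighborhood order, one of 4, 8, 12.
#' @param periodic wrap around the lattice edges (default `TRUE`).
#' @param offsets optional custom neighbor offset matrix (n x 2 of row/col
#'   offsets) overriding `k`; must be symmetric (contain `-o` for every `o`).
#' @return An object of class `io_topology`: rows, cols, k, periodic flag,
#'   the offset list and the `N x k` neighbor index matrix (0 marks a missing
#'   neighbor on non-periodic borders).
#' @examples
#' top <- build_topology(5, 5, k = 4)
#' sum(top$nbr > 0) / 2 # edge count
#' @export
build_topology <- function(rows, cols, k = 4, periodic = TRUE,
                           offsets = NULL) {
  if (rows < 3 || cols < 3) stop("'rows' and 'cols' must be >= 3")
  if (is.null(offsets)) {
    if (!k %in% c(4, 8, 12))
      stop("unsupported neighborhood order 'k' (use 4, 8 or 12)")
    off <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
    if (k >= 8)
      off <- rbind(off, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
    if (k == 12)
      off <- rbind(off, c(-2, 0), c(2, 0), c(0, -2), c(0, 2))
  } else {
    off <- as.matrix(offsets)
    k <- nrow(off)
    have <- paste(off[, 1], off[, 2])
    need <- paste(-off[, 1], -off[, 2])
    if (!all(need %in% have))
      stop("custom offsets must be symmetric under negation")
  }
  N <- rows * cols
  r <- rep(seq_len(rows), each = cols)
  c_ <- rep(seq_len(cols), times = rows)
  nbr <- matrix(0L, N, k)
  for (q in seq_len(k)) {
    rr <- r + off[q, 1]
    cc <- c_ + off[q, 2]
    if (periodic) {
      rr <- (rr - 1) %% rows + 1
      cc <- (cc - 1) %% cols + 1
      nbr[, q] <- (rr - 1L) * cols + cc
    } else {
      ok <- rr >= 1 & rr <= rows & cc >= 1 & cc <= cols
      nbr[ok, q] <- (rr[ok] - 1L) * cols + cc[ok]
    }
  }
  structure(list(rows = rows, cols = cols, k = k, periodic = periodic,
                 offsets = off, nbr = nbr),
            class = "io_topology")
}

#' @export
print.io_topology <- function(x, ...) {
  cat(sprintf("IO lattice: %d x %d, %d-neighbor coupling, %s boundaries\n",
              x$rows, x$cols, x$k,
              if (x$periodic) "periodic" else "open"))
  cat(sprintf("  cells: %d, gap-junction edges: %d\n",
              x$rows * x$cols, sum(x$nbr > 0) / 2))
  invisible(x)
}

#' Gap-junction coupling current over the lattice
#'
#' Diffusive electrical coupling: each cell receives
#' `I_elec = g_c * sum_i (V - V_i)` over its neighbors `i`. The current is
#' antisymmetric over each edge, so it sums to zero over the network and
#' vanishes on a uniform field.
#'
#' @param V membrane potential field: a `rows x cols` matrix or a length-N
#'   vector in row-major cell order.
#' @param topology an [build_topology()] object.
#' @param g_c electrical coupling conductance density (mS/cm^2), `>= 0`.
#' @return `I_elec` per cell (uA/cm^2), in the same shape as `V`.
#' @export
electrical_coupling <- function(V, topology, g_c) {
  if (g_c < 0) stop("'g_c' must be >= 0")
  N <- topology$rows * topology$cols
  vm <- if (is.matrix(V)) as.vector(t(V)) else as.vector(V)
  if (length(vm) != N) stop("'V' does not match the lattice dimensions")
  vpad <- c(0, vm)
  nb <- topology$nbr
  smat <- matrix(vpad[nb + 1L], nrow = N)
  deg <- rowSums(nb > 0L)
  iel <- g_c * (deg * vm - rowSums(smat))
  if (is.matrix(V))
    matrix(iel, topology$rows, topology$cols, byrow = TRUE)
  else iel
}

#' Specify a stimulus / excitability cluster
#'
#' A rectangular cluster of cells whose injected current and/or excitability
#' offset are overridden during a time window. Clusters are used to implement
#' external stimuli (e.g. two 6 x 6 clusters with different `I_inj`) and
#' low-excitability regions (`sigma = 2`, `I_inj = 0`) for the source-sink
#' protocols.
#'
#' @param origin top-left corner `c(row, col)`, 1-based; the cluster wraps
#'   around periodic boundaries.
#' @param height,width cluster extent in cells.
#' @param I_inj overriding injected current (uA/cm^2), or `NULL` to keep the
#'   baseline.
#' @param sigma overriding excitability offset, or `NULL`.
#' @param t_on,t_off time window (ms) during which the override applies;
#'   the default covers the whole run.
#' @return An object of class `io_cluster`.
#' @export
cluster_spec <- function(origin, height, width, I_inj = NULL, sigma = NULL,
                         t_on = 0, t_off = Inf) {
  if (length(origin) != 2) stop("'origin' must be c(row, col)")
  if (height < 1 || width < 1) stop("cluster extent must be >= 1")
  if (t_on >= t_off) stop("'t_on' must be < 't_off'")
  structure(list(origin = as.numeric(origin), height = height, width = width,
                 I_inj = I_inj, sigma = sigma, t_on = t_on, t_off = t_off),
            class = "io_cluster")
}

#' Cell indices covered by a cluster
#'
#' @param topology an [build_topology()] object.
#' @param cluster an [cluster_spec()] object.
#' @return Integer vector of 1-based cell indices (row-major), wrapping
#'   around periodic boundaries.
#' @export
cluster_cells <- function(topology, cluster) {
  if (cluster$height > topology$rows || cluster$width > topology$cols)
    stop("cluster does not fit within the lattice")
  r <- (cluster$origin[1] - 1 + seq_len(cluster$height) - 1) %% topology$rows + 1
  c_ <- (cluster$origin[2] - 1 + seq_len(cluster$width) - 1) %% topology$cols + 1
  as.integer(outer((r - 1) * topology$cols, c_, "+"))
}

#' Effective drive (injected current and excitability) at a time point
#'
#' Applies cluster overrides to the baseline per-cell maps. Overrides are
#' active only within `[t_on, t_off)`; when clusters overlap, the
#' last-listed cluster wins.
#'
#' @param topology an [build_topology()] object.
#' @param clusters list of [cluster_spec()] objects.
#' @param t time (ms).
#' @param I_base baseline injected current: scalar or length-N vector.
#' @param sigma_base baseline excitability offset: scalar or length-N vector.
#' @return A list with per-cell vectors `I_inj` and `sigma`.
#' @export
effective_drive <- function(topology, clusters, t, I_base, sigma_base) {
  N <- topology$rows * topology$cols
  I <- rep_len(I_base, N)
  sg <- rep_len(sigma_base, N)
  for (cl in clusters) {
    if (t < cl$t_on || t >= cl$t_off) next
    idx <- cluster_cells(topology, cl)
    if (!is.null(cl$I_inj)) I[idx] <- cl$I_inj
    if (!is.null(cl$sigma)) sg[idx] <- cl$sigma
  }
  list(I_inj = I, sigma = sg)
}

# piecewise-constant drive epochs over [0, duration): breakpoints at every
# cluster window edge
.drive_epochs <- function(topology, clusters, I_base, sigma_base, duration) {
  bp <- 0
  for (cl in clusters) {
    if (cl$t_on > 0 && cl$t_on < duration) bp <- c(bp, cl$t_on)
    if (is.finite(cl$t_off) && cl$t_off < duration) bp <- c(bp, cl$t_off)
  }
  bp <- sort(unique(bp))
  N <- topology$rows * topology$cols
  Imat <- matrix(0, length(bp), N)
  Smat <- matrix(0, length(bp), N)
  for (i in seq_along(bp)) {
    d <- effective_drive(topology, clusters, bp[i], I_base, sigma_base)
    Imat[i, ] <- d$I_inj
    Smat[i, ] <- d$sigma
  }
  list(start = bp, I_inj = Imat, sigma = Smat)
}
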