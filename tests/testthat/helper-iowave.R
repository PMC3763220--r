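# shared fixtures: a coherent-state library for the default cell, built once
# per test session (single-cell integration, a few seconds)
ic_lib_default <- local({
  lib <- NULL
  function() {
    if (is.null(lib)) lib <<- build_ic_library(n = 2000, seed = 101)
    lib
  }
})

# fast integrator settings used by network tests
test_integrator <- function(max_error = 1e-8, dt_record = 0.5)
  integrator_config(max_error = max_error, dt_max = 1, dt_record = dt_record)

# independent circumcenter construction: perpendicular-bisector intersection
circumcenter_oracle <- function(p1, p2, p3) {
  m12 <- (p1 + p2) / 2
  m13 <- (p1 + p3) / 2
  d12 <- p2 - p1
  d13 <- p3 - p1
  A <- rbind(d12, d13)
  b <- c(sum(d12 * m12), sum(d13 * m13))
  ctr <- solve(A, b)
  list(center = ctr, radius = sqrt(sum((p1 - ctr)^2)))
}

# independent integer-midpoint (Bresenham) circle rasterization for integer
# center and radius
bresenham_circle <- function(r0, c0, radius) {
  x <- radius
  y <- 0
  err <- 1 - radius
  pts <- NULL
  while (x >= y) {
    pts <- rbind(pts,
                 c(r0 + x, c0 + y), c(r0 + y, c0 + x),
                 c(r0 - y, c0 + x), c(r0 - x, c0 + y),
                 c(r0 - x, c0 - y), c(r0 - y, c0 - x),
                 c(r0 + y, c0 - x), c(r0 + x, c0 - y))
    y <- y + 1
    if (err < 0) err <- err + 2 * y + 1
    else {
      x <- x - 1
      err <- err + 2 * (y - x) + 1
    }
  }
  unique(pts)
}

# non-standard 2D Haar coefficients by direct construction of the
# Cartesian-product basis (quad-tree levels, same scale in both directions)
haar2d_basis_oracle <- function(frame) {
  side <- nrow(frame)
  L <- log2(side)
  phi <- function(j, k) { # scaling function at block size 2^j, block k
    v <- numeric(side)
    v[((k - 1) * 2^j + 1):(k * 2^j)] <- 2^(-j / 2)
    v
  }
  psi <- function(j, k) {
    v <- numeric(side)
    idx <- ((k - 1) * 2^j + 1):(k * 2^j)
    half <- length(idx) / 2
    v[idx[seq_len(half)]] <- 2^(-j / 2)
    v[idx[half + seq_len(half)]] <- -2^(-j / 2)
    v
  }
  coefs <- sum(frame * outer(phi(L, 1), phi(L, 1)))
  for (j in seq_len(L)) {
    nb <- side / 2^j
    for (k in seq_len(nb)) for (l in seq_len(nb)) {
      coefs <- c(coefs,
                 sum(frame * outer(psi(j, k), phi(j, l))),
                 sum(frame * outer(phi(j, k), psi(j, l))),
                 sum(frame * outer(psi(j, k), psi(j, l))))
    }
  }
  coefs
}
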