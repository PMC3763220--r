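test_that("binarization is a strict threshold comparison", {
  f <- matrix(-60, 4, 4)
  expect_true(all(!binarize(f)))
  expect_true(all(!binarize(matrix(-47, 4, 4)))) # boundary: strict >
  f[2, 3] <- 0
  b <- binarize(f)
  expect_equal(sum(b), 1)
  expect_true(b[2, 3])
})

test_that("circle fitting solves the three-point system", {
  res <- circle_through_points(c(0, 1), c(1, 0), c(0, -1))
  expect_equal(res$center, c(0, 0))
  expect_equal(res$radius, 1)
  expect_false(res$collinear)
  expect_true(circle_through_points(c(0, 0), c(1, 1), c(2, 2))$collinear)
  # residual of all three points below 1e-9
  set.seed(31)
  for (rep in 1:20) {
    P <- matrix(runif(6, -20, 20), 3, 2)
    res <- circle_through_points(P[1, ], P[2, ], P[3, ])
    if (res$collinear) next
    resid <- abs(sqrt(rowSums((P - rep(res$center, each = 3))^2)) -
                   res$radius)
    expect_lt(max(resid), 1e-9)
  }
})

test_that("circle fitting agrees with the circumcenter construction", {
  set.seed(32)
  worst <- 0
  for (rep in 1:1000) {
    P <- matrix(runif(6, 0, 50), 3, 2)
    res <- circle_through_points(P[1, ], P[2, ], P[3, ])
    if (res$collinear) next
    ora <- circumcenter_oracle(P[1, ], P[2, ], P[3, ])
    worst <- max(worst, max(abs(res$center - ora$center)),
                 abs(res$radius - ora$radius))
  }
  expect_lt(worst, 1e-8)
})

test_that("rasterized circles match an integer midpoint-algorithm oracle", {
  for (r in c(4, 8, 13)) {
    mine <- rasterize_circle(c(25, 25), r, 50, 50)
    ora <- bresenham_circle(25, 25, r)
    key <- function(m) sort(paste(m[, 1], m[, 2]))
    expect_setequal(key(mine), key(ora))
  }
})

test_that("the detector recovers rasterized circles with tight error", {
  fx <- make_fixture("expanding_ring", center = c(25, 25),
                     radii = rep(8, 1), n_frames = 1)
  a <- detect_arcs(binarize(fx$frames[1, , ]), seed = 41)
  expect_equal(nrow(a), 1)
  expect_lt(abs(a$center_row - 25), 1)
  expect_lt(abs(a$center_col - 25), 1)
  expect_lt(abs(a$radius - 8), 1)
  # empty frame
  expect_equal(nrow(detect_arcs(matrix(FALSE, 20, 20), seed = 1)), 0)
  # two disjoint circles both recovered
  fx2 <- make_fixture("two_circles", center = list(c(15, 15), c(38, 38)),
                      radii = c(6, 8), n_frames = 1)
  a2 <- detect_arcs(binarize(fx2$frames[1, , ]), seed = 42)
  expect_equal(nrow(a2), 2)
  got <- a2[order(a2$center_row), ]
  expect_lt(max(abs(got$center_row - c(15, 38))), 1)
  expect_lt(max(abs(got$center_col - c(15, 38))), 1)
  # determinism
  b1 <- detect_arcs(binarize(fx2$frames[1, , ]), seed = 43)
  b2 <- detect_arcs(binarize(fx2$frames[1, , ]), seed = 43)
  expect_identical(b1, b2)
})

test_that("detector recall and center error hold under salt noise", {
  hits <- 0
  n_tot <- 0
  for (sd in 1:10) {
    fx <- make_fixture("expanding_ring", center = c(25, 25),
                       radii = c(6, 9, 12), n_frames = 3, noise = 0.1,
                       seed = sd)
    for (i in 1:3) {
      n_tot <- n_tot + 1
      a <- detect_arcs(binarize(fx$frames[i, , ]), seed = 100 + sd * 10 + i)
      if (!nrow(a)) next
      err <- sqrt((a$center_row - 25)^2 + (a$center_col - 25)^2)
      j <- which.min(err)
      if (err[j] <= 1.5 && abs(a$radius[j] - fx$annotations$radius[i]) <= 2)
        hits <- hits + 1
    }
  }
  expect_gte(hits / n_tot, 0.9)
})

test_that("tracking links expanding rings and rejects unordered input", {
  fx <- make_fixture("expanding_ring", center = c(25, 25),
                     radii = seq(2, 14, length.out = 5), n_frames = 5)
  arcs <- detect_arcs_stack(fx$frames, stride = 1, seed = 51)
  tr <- track_arcs(arcs, center_tol = 5)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_true(all(diff(tr$radius) > 0))
  expect_error(track_arcs(arcs[rev(seq_len(nrow(arcs))), ]), "ordered")
  # two far-apart static circles never cross-link
  fx2 <- make_fixture("two_circles", center = list(c(12, 12), c(38, 38)),
                      radii = c(5, 5), n_frames = 4)
  arcs2 <- detect_arcs_stack(fx2$frames, stride = 1, seed = 52)
  tr2 <- track_arcs(arcs2, center_tol = 5)
  expect_equal(length(unique(tr2$track_id)), 2)
  for (id in unique(tr2$track_id)) {
    g <- tr2[tr2$track_id == id, ]
    expect_lt(diff(range(g$center_row)), 2)
  }
})

test_that("sources and sinks are classified and attributed from fixtures", {
  top <- build_topology(50, 50, 4)
  clusters <- list(A = cluster_spec(c(22, 22), 6, 6),
                   B = cluster_spec(c(35, 35), 6, 6))
  # expanding ring born in cluster A
  fx <- make_fixture("expanding_ring", center = c(24, 24),
                     radii = seq(2, 14, length.out = 7), n_frames = 7)
  arcs <- detect_arcs_stack(fx$frames, stride = 1, seed = 61,
                            times = seq(0, 60, by = 10))
  rep <- classify_and_report(track_arcs(arcs, center_tol = 5), clusters, top,
                             sample_interval = 10)
  expect_equal(rep$tracks$class, "source")
  expect_equal(rep$tracks$cluster, "A")
  src <- rep$report[rep$report$role == "source", ]
  expect_true(all(diff(src$mean_radius[src$n > 0]) > 0))
  expect_equal(rep$attribution$frac_expanding_at_source[1], 1)
  # contracting ring dying in cluster B
  fx2 <- make_fixture("contracting_ring", center = c(37, 37),
                      radii = seq(14, 2, length.out = 7), n_frames = 7)
  arcs2 <- detect_arcs_stack(fx2$frames, stride = 1, seed = 62,
                             times = seq(0, 60, by = 10))
  rep2 <- classify_and_report(track_arcs(arcs2, center_tol = 5), clusters,
                              top, sample_interval = 10)
  expect_equal(rep2$tracks$class, "sink")
  expect_equal(rep2$tracks$cluster, "B")
  snk <- rep2$report[rep2$report$role == "sink", ]
  expect_true(all(diff(snk$mean_radius[snk$n > 0]) < 0))
  expect_equal(
    rep2$attribution$frac_shrinking_at_sink[rep2$attribution$cluster == "B"],
    1)
  # no tracks: a valid empty report
  empty <- classify_and_report(track_arcs(arcs[0, ]), clusters, top)
  expect_s3_class(empty, "io_sourcesink")
  expect_equal(nrow(empty$report), 0)
})
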