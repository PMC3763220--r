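scenario_path <- function(name)
  system.file("extdata", "scenarios", paste0(name, ".yaml"),
              package = "iowave")

test_that("bundled scenarios load with their published settings", {
  sc <- load_scenario(scenario_path("moderate_coupling"))
  expect_equal(sc$lattice$rows, 50)
  expect_equal(sc$lattice$cols, 50)
  expect_equal(sc$lattice$k, 4)
  expect_equal(sc$g_c, 0.05)
  sa <- load_scenario(scenario_path("source_sink_SA"))
  expect_equal(sa$lattice$k, 12)
  expect_equal(sa$g_c, 0.01)
  expect_length(sa$clusters, 2)
  expect_equal(sa$clusters[[2]]$sigma, 2)
  expect_equal(sa$clusters[[2]]$I_inj, 0)
})

test_that("schema violations are rejected with the offending keys", {
  f <- tempfile(fileext = ".yaml")
  writeLines("", f)
  expect_error(load_scenario(f), "empty")
  writeLines(c("name: x", "gc_typo: 0.05"), f)
  expect_error(load_scenario(f), "gc_typo")
  writeLines(c("name: x", "lattice: {rows: 10, colz: 10}"), f)
  expect_error(load_scenario(f), "colz")
  expect_error(load_scenario(tempfile()), "not found")
})

test_that("scenario save/load round-trips", {
  sc <- load_scenario(scenario_path("source_sink_SA"))
  f <- tempfile(fileext = ".yaml")
  save_scenario(sc, f)
  sc2 <- load_scenario(f)
  expect_equal(sc2$lattice, sc$lattice)
  expect_equal(sc2$g_c, sc$g_c)
  expect_equal(sc2$duration, sc$duration)
  expect_equal(length(sc2$clusters), length(sc$clusters))
  expect_equal(sc2$clusters[[1]]$I_inj, sc$clusters[[1]]$I_inj)
  expect_equal(sc2$integrator$max_error, sc$integrator$max_error)
})

test_that("every bundled scenario loads and runs at reduced duration", {
  lib <- ic_lib_default()
  files <- list.files(system.file("extdata", "scenarios", package = "iowave"),
                      full.names = TRUE)
  expect_gte(length(files), 10)
  for (f in files) {
    sc <- load_scenario(f)
    sc$lattice$rows <- 12
    sc$lattice$cols <- 12
    sc$clusters <- lapply(sc$clusters, function(cl) {
      cl$origin <- c(cl$origin[1] %% 12 + 1, cl$origin[2] %% 12 + 1)
      cl$height <- min(cl$height, 4)
      cl$width <- min(cl$width, 4)
      cl
    })
    rec <- run_scenario(sc, duration = 10, seed = 1, ic_library = lib)
    expect_s3_class(rec, "io_record")
    expect_equal(dim(rec$frames)[2:3], c(12, 12), info = f)
  }
})

test_that("records round-trip bit-exactly through write/read", {
  lib <- ic_lib_default()
  top <- build_topology(5, 5, 4)
  rec <- simulate_network(top, 0.05, 60, ic_library = lib, seed = 71,
                          integrator = test_integrator())
  f <- tempfile(fileext = ".rds")
  write_record(rec, f)
  rec2 <- read_record(f)
  expect_identical(rec2$frames, rec$frames)
  expect_identical(rec2$spikes, rec$spikes)
  # CSV export carries the same numbers
  fc <- tempfile(fileext = ".csv")
  export_frames_csv(rec, fc)
  df <- utils::read.csv(fc)
  expect_equal(df$t_ms, rec$times)
  expect_equal(df$cell0007[3], rec$frames[3, 2, 2], tolerance = 1e-12)
  fs <- tempfile(fileext = ".csv")
  export_spikes_csv(rec, fs)
  sp <- utils::read.csv(fs)
  expect_equal(nrow(sp), nrow(rec$spikes))
})

test_that("rendering maps potentials to the threshold-anchored colormap", {
  rec <- structure(list(
    frames = array(-60, c(3, 8, 8)), times = c(0, 0.5, 1),
    topology = list(rows = 8, cols = 8), duration = 1,
    integrator = integrator_config(max_error = 1e-8)),
    class = "io_record")
  d <- tempfile()
  paths <- render_frames(rec, d)
  expect_length(paths, 3)
  img <- png::readPNG(paths[1])
  expect_equal(dim(img)[1:2], c(8, 8))
  # uniform frame renders in a single color
  expect_equal(length(unique(as.vector(img[, , 1]))), 1)
  # one suprathreshold cell renders exactly one warm (red-dominant) pixel
  rec$frames[1, 3, 5] <- 0
  paths <- render_frames(rec, d)
  img <- png::readPNG(paths[1])
  warm <- img[, , 1] > img[, , 3] # red channel exceeds blue
  expect_equal(sum(warm), 1)
  expect_true(warm[3, 5])
  # stride halves the frame count, rounding up
  paths <- render_frames(rec, d, render_spec(stride = 2))
  expect_length(paths, 2)
})

test_that("fixture stacks honor geometry, determinism and bounds", {
  fx <- make_fixture("uniform", rows = 10, cols = 10, n_frames = 3)
  expect_true(all(fx$frames == -60))
  n1 <- make_fixture("expanding_ring", rows = 30, cols = 30, noise = 0.2,
                     center = c(15, 15), radii = rep(5, 2), n_frames = 2,
                     seed = 9)
  n2 <- make_fixture("expanding_ring", rows = 30, cols = 30, noise = 0.2,
                     center = c(15, 15), radii = rep(5, 2), n_frames = 2,
                     seed = 9)
  expect_identical(n1$frames, n2$frames)
  expect_error(make_fixture("expanding_ring", rows = 20, cols = 20,
                            center = c(10, 10), radii = c(2, 15),
                            n_frames = 2),
               "exceeds")
  # ring pixel counts annotated from the raster
  fx <- make_fixture("expanding_ring", center = c(25, 25),
                     radii = c(4, 8), n_frames = 2)
  for (i in 1:2)
    expect_equal(sum(fx$frames[i, , ] > -47), fx$annotations$n_pixels[i])
})
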