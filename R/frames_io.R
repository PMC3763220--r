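# recognized scenario keys (unknown keys are rejected)
.SCENARIO_KEYS <- list(
  top = c("name", "lattice", "g_c", "duration", "seed", "cell", "baseline",
          "clusters", "il", "integrator"),
  lattice = c("rows", "cols", "k", "periodic"),
  cell = c("C_m", "g_l", "V_l", "gbar_Na", "gbar_Nap", "gbar_Kd", "gbar_Ks",
           "gbar_h", "V_Na", "V_K", "V_h", "rho", "sigma", "I_inj",
           "alpha_c_pref"),
  baseline = c("I_inj", "sigma"),
  cluster = c("origin", "height", "width", "I_inj", "sigma", "t_on", "t_off"),
  il = c("enabled", "window", "delay", "refractory", "p_conn", "max_cluster",
         "gbar_syn", "membrane_area", "E_syn", "alpha", "beta", "T_conc",
         "T_dur", "sync_fraction", "check_dt"),
  integrator = c("max_error", "dt_max", "dt_record"))

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("scenario schema violation in '%s': unknown key(s) %s",
                 where, paste(sQuote(bad), collapse = ", ")))
}

#' Load and validate a scenario configuration
#'
#' Scenarios are human-readable YAML files describing a complete simulation
#' protocol: lattice, coupling, cell-parameter overrides, baseline drive,
#' stimulus clusters, inhibitory loop and integrator settings. Unknown keys
#' are rejected; all defaults are filled in and echoed back. Bundled
#' scenarios live under `system.file("extdata", "scenarios", package =
#' "iowave")`.
#'
#' @param path path to a YAML scenario file.
#' @return An object of class `io_scenario` (fully defaulted configuration).
#' @examples
#' sc <- load_scenario(system.file("extdata", "scenarios",
#'                                 "moderate_coupling.yaml",
#'                                 package = "iowave"))
#' sc$g_c
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || !length(raw)) stop("scenario schema violation: empty file")
  as_scenario(raw)
}

#' Build a scenario configuration from a list
#'
#' @param x named list with the scenario keys (see [load_scenario()]).
#' @return An `io_scenario` with all defaults filled.
#' @export
as_scenario <- function(x) {
  .check_keys(x, .SCENARIO_KEYS$top, "top level")
  lat <- x$lattice
  if (is.null(lat)) lat <- list()
  .check_keys(lat, .SCENARIO_KEYS$lattice, "lattice")
  lat <- utils::modifyList(list(rows = 50, cols = 50, k = 4,
                                periodic = TRUE), lat)
  cellov <- x$cell
  if (is.null(cellov)) cellov <- list()
  .check_keys(cellov, .SCENARIO_KEYS$cell, "cell")
  base <- x$baseline
  if (is.null(base)) base <- list()
  .check_keys(base, .SCENARIO_KEYS$baseline, "baseline")
  base <- utils::modifyList(list(I_inj = c(0, 0.35), sigma = NULL), base)
  clusters <- lapply(seq_along(x$clusters), function(i) {
    cl <- x$clusters[[i]]
    .check_keys(cl, .SCENARIO_KEYS$cluster, sprintf("clusters[%d]", i))
    do.call(cluster_spec, utils::modifyList(
      list(t_on = 0, t_off = Inf), cl))
  })
  il <- x$il
  if (!is.null(il)) {
    .check_keys(il, .SCENARIO_KEYS$il, "il")
    enabled <- isTRUE(il$enabled) || is.null(il$enabled)
    il$enabled <- NULL
    il <- if (enabled) do.call(il_parameters, il) else NULL
  }
  integ <- x$integrator
  if (is.null(integ)) integ <- list()
  .check_keys(integ, .SCENARIO_KEYS$integrator, "integrator")
  integ <- do.call(integrator_config,
                   utils::modifyList(list(max_error = 1e-8), integ))
  structure(list(name = if (is.null(x$name)) "scenario" else x$name,
                 lattice = lat, g_c = if (is.null(x$g_c)) 0.05 else x$g_c,
                 duration = if (is.null(x$duration)) 2000 else x$duration,
                 seed = x$seed, cell = cellov, baseline = base,
                 clusters = clusters, il = il, integrator = integ),
            class = "io_scenario")
}

#' Save a scenario configuration
#'
#' Round-trips through [load_scenario()]: saving and re-loading reproduces
#' the same configuration.
#'
#' @param scenario an `io_scenario`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_scenario <- function(scenario, path) {
  out <- list(name = scenario$name, lattice = scenario$lattice,
              g_c = scenario$g_c, duration = scenario$duration)
  if (!is.null(scenario$seed)) out$seed <- scenario$seed
  if (length(scenario$cell)) out$cell <- scenario$cell
  bl <- scenario$baseline
  bl <- bl[!vapply(bl, is.null, TRUE)]
  if (length(bl)) out$baseline <- bl
  if (length(scenario$clusters))
    out$clusters <- lapply(scenario$clusters, function(cl) {
      v <- list(origin = cl$origin, height = cl$height, width = cl$width)
      if (!is.null(cl$I_inj)) v$I_inj <- cl$I_inj
      if (!is.null(cl$sigma)) v$sigma <- cl$sigma
      if (cl$t_on != 0) v$t_on <- cl$t_on
      if (is.finite(cl$t_off)) v$t_off <- cl$t_off
      v
    })
  if (!is.null(scenario$il)) {
    il <- unclass(scenario$il)
    il$gsyn_density <- NULL
    out$il <- c(list(enabled = TRUE), il)
  }
  out$integrator <- unclass(scenario$integrator)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run a scenario
#'
#' @param scenario an `io_scenario` object or path to a scenario file.
#' @param duration,seed optional overrides of the scenario values.
#' @param ... further arguments to [simulate_network()] (e.g. `ic_library`).
#' @return An [simulate_network()] record.
#' @export
run_scenario <- function(scenario, duration = NULL, seed = NULL, ...) {
  if (is.character(scenario)) scenario <- load_scenario(scenario)
  params <- do.call(cell_parameters, scenario$cell)
  top <- build_topology(scenario$lattice$rows, scenario$lattice$cols,
                        scenario$lattice$k, scenario$lattice$periodic)
  if (!is.null(scenario$baseline$sigma)) params$sigma <- scenario$baseline$sigma
  simulate_network(
    topology = top, g_c = scenario$g_c,
    duration = if (is.null(duration)) scenario$duration else duration,
    params = params, clusters = scenario$clusters,
    I_baseline = unlist(scenario$baseline$I_inj),
    il_params = scenario$il,
    integrator = scenario$integrator,
    seed = if (is.null(seed)) scenario$seed else seed, ...)
}

#' Persist and reload simulation records
#'
#' Records round-trip bit-exactly (frames) through R serialization; frames
#' and spikes can additionally be exported as plain CSV for analysis outside
#' R.
#'
#' @param record an [simulate_network()] record.
#' @param path output path (`.rds`).
#' @return `path` invisibly ([write_record()]); the record ([read_record()]).
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "io_record"))
  saveRDS(record, path)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  rec <- readRDS(path)
  if (!inherits(rec, "io_record")) stop("not an io_record file")
  rec
}

#' Export frames or spikes as CSV
#'
#' @param record an [simulate_network()] record.
#' @param path output CSV path.
#' @param stride export every `stride`-th frame.
#' @return `path`, invisibly.
#' @export
export_frames_csv <- function(record, path, stride = 1) {
  sel <- seq(1, length(record$times), by = stride)
  N <- record$topology$rows * record$topology$cols
  m <- matrix(aperm(record$frames[sel, , , drop = FALSE], c(1, 3, 2)),
              nrow = length(sel))
  df <- data.frame(t_ms = record$times[sel], m)
  names(df) <- c("t_ms", sprintf("cell%04d", seq_len(N)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_frames_csv
#' @export
export_spikes_csv <- function(record, path) {
  utils::write.csv(record$spikes, path, row.names = FALSE)
  invisible(path)
}

# colormap anchored at the firing threshold: cool colors below (blue scale),
# warm colors above (yellow to red)
.activity_palette <- function(n, v_min = -80, v_max = 20, threshold = -47) {
  n_cool <- max(1, round(n * (threshold - v_min) / (v_max - v_min)))
  n_warm <- max(1, n - n_cool)
  cool <- grDevices::colorRampPalette(c("#00004B", "#0050C8", "#00C8E6"))(n_cool)
  warm <- grDevices::colorRampPalette(c("#FFE100", "#FF7800", "#D20000"))(n_warm)
  c(cool, warm)
}

#' Rendering settings
#'
#' Monotone colormap anchored at the firing threshold: cool colors (blue)
#' for hyperpolarized potentials, warm colors (yellow to red) above the
#' threshold, graded subthreshold values in between.
#'
#' @param v_min,v_max color range (mV).
#' @param threshold firing threshold anchoring the warm/cool boundary (mV).
#' @param stride render every `stride`-th frame.
#' @return An object of class `io_render_spec`.
#' @export
render_spec <- function(v_min = -80, v_max = 20, threshold = -47,
                        stride = 1) {
  if (v_min >= v_max) stop("'v_min' must be < 'v_max'")
  structure(list(v_min = v_min, v_max = v_max, threshold = threshold,
                 stride = stride),
            class = "io_render_spec")
}

#' Render record frames as a PNG sequence
#'
#' One PNG per selected frame, deterministic for a fixed spec; a diagnostic
#' view of the propagating patterns (analyses always consume the raw mV
#' frames).
#'
#' @param record an [simulate_network()] record.
#' @param out_dir output directory (created if missing).
#' @param spec an [render_spec()].
#' @return Character vector of written file paths, invisibly.
#' @export
render_frames <- function(record, out_dir, spec = render_spec()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pal <- .activity_palette(256, spec$v_min, spec$v_max, spec$threshold)
  rgb <- grDevices::col2rgb(pal) / 255
  sel <- seq(1, length(record$times), by = spec$stride)
  paths <- character(length(sel))
  for (i in seq_along(sel)) {
    f <- record$frames[sel[i], , ]
    v <- pmin(pmax(f, spec$v_min), spec$v_max)
    bin <- pmin(256L, pmax(1L, 1L + as.integer(
      floor((v - spec$v_min) / (spec$v_max - spec$v_min) * 256))))
    img <- array(0, c(nrow(f), ncol(f), 3))
    for (ch in 1:3)
      img[, , ch] <- matrix(rgb[ch, bin], nrow(f), ncol(f))
    paths[i] <- file.path(out_dir, sprintf("frame_%06d.png", sel[i]))
    png::writePNG(img, paths[i])
  }
  invisible(paths)
}

#' Synthetic frame-stack fixtures with ground truth
#'
#' Generates annotated activity stacks for exercising the wavelet and
#' wave-front analyses independently of the simulator: expanding or
#' contracting rings (one-pixel-wide rasterized circles on a resting
#' background), uniform fields, checkerboard noise, and two static circles.
#'
#' @param kind one of `"expanding_ring"`, `"contracting_ring"`, `"uniform"`,
#'   `"checkerboard_noise"`, `"two_circles"`.
#' @param rows,cols lattice size.
#' @param n_frames number of frames.
#' @param center ring center `c(row, col)` (first kinds); for
#'   `"two_circles"` a list of two centers.
#' @param radii per-frame radii; defaults to a linear sweep 2..14
#'   (expanding) or 14..2 (contracting); for `"two_circles"` a length-2
#'   vector of static radii.
#' @param value_on,value_off suprathreshold and resting values (mV).
#' @param noise salt-noise fraction: each background pixel independently set
#'   to `value_on` with this probability per frame.
#' @param amplitude checkerboard amplitude (mV) around `value_off`.
#' @param seed RNG seed for the noise realization.
#' @return A list of class `io_fixture`: `frames` (n_frames x rows x cols),
#'   `annotations` (per-frame ground truth) and `kind`.
#' @export
make_fixture <- function(kind = c("expanding_ring", "contracting_ring",
                                  "uniform", "checkerboard_noise",
                                  "two_circles"),
                         rows = 50, cols = 50, n_frames = 5,
                         center = c(25, 25), radii = NULL,
                         value_on = 0, value_off = -60,
                         noise = 0, amplitude = 3, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  frames <- array(value_off, c(n_frames, rows, cols))
  ann <- NULL
  if (kind %in% c("expanding_ring", "contracting_ring")) {
    if (is.null(radii))
      radii <- if (kind == "expanding_ring")
        seq(2, 14, length.out = n_frames)
      else seq(14, 2, length.out = n_frames)
    if (length(radii) != n_frames) stop("'radii' must have one value per frame")
    if (max(radii) >= min(rows, cols) / 2 - 1)
      stop("ring exceeds the lattice")
    ann <- data.frame(frame = seq_len(n_frames), center_row = center[1],
                      center_col = center[2], radius = radii,
                      n_pixels = NA_integer_)
    for (i in seq_len(n_frames)) {
      px <- rasterize_circle(center, radii[i], rows, cols)
      f <- frames[i, , ]
      f[px] <- value_on
      frames[i, , ] <- f
      ann$n_pixels[i] <- nrow(px)
    }
  } else if (kind == "uniform") {
    frames[] <- value_off
    ann <- data.frame(frame = seq_len(n_frames), value = value_off)
  } else if (kind == "checkerboard_noise") {
    chk <- outer(seq_len(rows), seq_len(cols),
                 function(r, c) amplitude * (-1)^(r + c))
    for (i in seq_len(n_frames))
      frames[i, , ] <- value_off + chk +
        matrix(stats::rnorm(rows * cols), rows, cols)
    ann <- data.frame(frame = seq_len(n_frames), amplitude = amplitude)
  } else { # two_circles
    if (!is.list(center)) center <- list(c(15, 15), c(38, 38))
    if (is.null(radii)) radii <- c(6, 8)
    ann <- do.call(rbind, lapply(seq_along(center), function(j)
      data.frame(frame = rep(seq_len(n_frames), each = 1),
                 center_row = center[[j]][1], center_col = center[[j]][2],
                 radius = radii[j], circle = j)))
    for (i in seq_len(n_frames)) {
      f <- frames[i, , ]
      for (j in seq_along(center)) {
        px <- rasterize_circle(center[[j]], radii[j], rows, cols)
        f[px] <- value_on
      }
      frames[i, , ] <- f
    }
  }
  if (noise > 0 && kind != "uniform") {
    for (i in seq_len(n_frames)) {
      f <- frames[i, , ]
      flip <- matrix(stats::runif(rows * cols) < noise, rows, cols) &
        f == value_off
      f[flip] <- value_on
      frames[i, , ] <- f
    }
  }
  structure(list(frames = frames, annotations = ann, kind = kind),
            class = "io_fixture")
}
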