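#' ESRI ASCII grid export/import of surfaces
#'
#' Writes one band of a surface as an ESRI ASCII grid (`NCOLS/NROWS/...`
#' header, rows from the top of the window down, nodata for knots outside
#' the window or non-evaluable). The format requires square cells, so the
#' grid's x and y steps must match. Values are printed with 10 significant
#' digits; a read-back reproduces the written surface to that precision.
#'
#' @param values An `nx` x `ny` matrix as stored in the surface objects
#'   (`[i, j]` at `(x[i], y[j])`), or a surface object together with `band`.
#' @param grid The [make_grid()] grid the values live on.
#' @param path Output path.
#' @param nodata Nodata sentinel written for NA cells.
#' @return `write_ascii_grid`: the path, invisibly. `read_ascii_grid`: a
#'   list with `values` (`nx` x `ny` matrix, NA at nodata), `nx`, `ny`,
#'   `xll`, `yll`, `cellsize`.
#' @export
write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "srr_grid"), is.matrix(values))
  if (abs(grid$xstep - grid$ystep) > 1e-9 * grid$xstep) {
    stop("ESRI ASCII grids need square cells (xstep == ystep)", call. = FALSE)
  }
  b <- grid$window$bbox
  hdr <- c(sprintf("NCOLS %d", grid$nx),
           sprintf("NROWS %d", grid$ny),
           sprintf("XLLCORNER %.10g", b[["xmin"]]),
           sprintf("YLLCORNER %.10g", b[["ymin"]]),
           sprintf("CELLSIZE %.10g", grid$xstep),
           sprintf("NODATA_VALUE %.10g", nodata))
  # ASCII grids run top row first; our columns index y ascending
  rows <- vapply(rev(seq_len(grid$ny)), function(j) {
    v <- values[, j]
    v[is.na(v)] <- nodata
    paste(formatC(v, format = "g", digits = 10), collapse = " ")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path, nodata = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[toupper(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  nx <- as.integer(hdr$NCOLS); ny <- as.integer(hdr$NROWS)
  nod <- if (!is.null(nodata)) nodata else hdr$NODATA_VALUE
  vals <- as.numeric(unlist(strsplit(trimws(lines[i:(i + ny - 1L)]), "\\s+")))
  m <- matrix(vals, nrow = nx, ncol = ny)   # one column per file row (top-down)
  m <- m[, rev(seq_len(ny)), drop = FALSE]  # back to y-ascending columns
  if (!is.null(nod)) m[m == nod] <- NA_real_
  list(values = m, nx = nx, ny = ny, xll = hdr$XLLCORNER,
       yll = hdr$YLLCORNER, cellsize = hdr$CELLSIZE)
}

#' Write a power surface to disk
#'
#' Writes the `power`, `n_eval` and `powered` bands as ESRI ASCII grids
#' plus a JSON metadata sidecar (`<stem>_meta.json`) holding the full run
#' configuration (window, models, grid, alpha, tails, threshold, n_iter,
#' seed, package version), sufficient to re-run the identical calculation
#' with [run_power()].
#'
#' @param psurf A `power_surface`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem (default `"power"`).
#' @return Invisibly, the paths written.
#' @export
write_power_surface <- function(psurf, dir, stem = "power") {
  stopifnot(inherits(psurf, "power_surface"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, paste0(stem, ".asc"))
  p2 <- file.path(dir, paste0(stem, "_n_eval.asc"))
  p3 <- file.path(dir, paste0(stem, "_powered.asc"))
  pm <- file.path(dir, paste0(stem, "_meta.json"))
  write_ascii_grid(psurf$power, psurf$grid, p1)
  ne <- psurf$n_eval; storage.mode(ne) <- "double"
  ne[!psurf$grid$inside] <- NA_real_
  write_ascii_grid(ne, psurf$grid, p2)
  pw <- ifelse(psurf$powered, 1, 0); pw[!psurf$grid$inside] <- NA_real_
  write_ascii_grid(pw, psurf$grid, p3)
  meta <- list(
    config = config_from_run(psurf),
    powered = list(n_knots = unname(powered_area(psurf)[["n_knots"]]),
                   area = unname(powered_area(psurf)[["area"]])),
    h_mean = psurf$h_mean,
    package = "srrpower",
    version = as.character(utils::packageVersion("srrpower")))
  jsonlite::write_json(meta, pm, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(power = p1, n_eval = p2, powered = p3, meta = pm))
}

## ---- run configuration --------------------------------------------------

#' Run configuration files
#'
#' A run configuration is a YAML (or JSON) document describing a complete
#' simulation/power run. Recognised keys (defaults in parentheses):
#'
#' * `window`: `{type: disc, center: [x, y], radius: r}`,
#'   `{type: rectangle, xmin, ymin, xmax, ymax}`, or
#'   `{type: geojson, path: file}`.
#' * `case_model` / `control_model`: `{type: mvn, centers, sigma, weights}`,
#'   `{type: csr}`, or `{type: uniform, center, radius}`.
#' * `n_case`, `n_control` — or `n_total` with `incidence_per_100k`, split
#'   via [split_by_incidence()].
#' * `grid`: `{nx (128), ny (128)}`; `n_iter` (10000); `alpha` (0.05);
#'   `tails` (`two`); `threshold` (0.8); `seed` (required);
#'   `edge_correct` (true).
#'
#' `read_config()` parses and fully validates the document before any
#' simulation starts; every invalid field produces an error naming the
#' field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @param overrides Named list of keys overriding the file's values (used by
#'   the command-line interface flags).
#' @return A validated config object (class `run_config`) with the window,
#'   models and all run parameters resolved.
#' @export
read_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  raw[names(overrides)] <- overrides
  validate_config(raw, dir = dirname(path))
}

#' @rdname read_config
#' @param raw A named list with the keys above.
#' @param dir Base directory for relative file references.
#' @export
validate_config <- function(raw, dir = ".") {
  fail <- function(field, why) {
    stop(sprintf("invalid config field '%s': %s", field, why), call. = FALSE)
  }
  if (is.null(raw$window)) fail("window", "missing")
  window <- window_from_config(raw$window, dir, fail)

  if (!is.null(raw$n_total) || !is.null(raw$incidence_per_100k)) {
    if (is.null(raw$n_total) || is.null(raw$incidence_per_100k)) {
      fail("n_total", "n_total and incidence_per_100k must be given together")
    }
    counts <- split_by_incidence(raw$n_total, raw$incidence_per_100k)
    n_case <- counts[["n_case"]]; n_control <- counts[["n_control"]]
  } else {
    n_case <- raw$n_case; n_control <- raw$n_control
    if (is.null(n_case) || is.null(n_control)) {
      fail("n_case", "give n_case and n_control, or n_total with incidence_per_100k")
    }
  }
  if (!is.numeric(n_case) || n_case < 1) fail("n_case", "must be >= 1")
  if (!is.numeric(n_control) || n_control < 1) fail("n_control", "must be >= 1")

  if (is.null(raw$case_model)) fail("case_model", "missing")
  if (is.null(raw$control_model)) fail("control_model", "missing")
  case_model <- model_from_config(raw$case_model, "case_model", fail)
  control_model <- model_from_config(raw$control_model, "control_model", fail)

  grid_nx <- raw$grid$nx %||% 128L
  grid_ny <- raw$grid$ny %||% 128L
  if (!is.numeric(grid_nx) || grid_nx < 2) fail("grid.nx", "must be >= 2")
  if (!is.numeric(grid_ny) || grid_ny < 2) fail("grid.ny", "must be >= 2")

  n_iter <- raw$n_iter %||% 10000L
  if (!is.numeric(n_iter) || n_iter < 1) fail("n_iter", "must be >= 1")
  alpha <- raw$alpha %||% 0.05
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    fail("alpha", "must be in (0, 1)")
  }
  tails <- raw$tails %||% "two"
  if (!tails %in% c("two", "upper", "lower")) {
    fail("tails", "must be one of two/upper/lower")
  }
  threshold <- raw$threshold %||% 0.8
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    fail("threshold", "must be in (0, 1]")
  }
  if (is.null(raw$seed)) fail("seed", "missing (required for reproducibility)")
  if (!is.numeric(raw$seed) || raw$seed != round(raw$seed)) {
    fail("seed", "must be an integer")
  }
  edge_correct <- raw$edge_correct %||% TRUE
  if (!is.logical(edge_correct)) fail("edge_correct", "must be true/false")

  scenario <- tryCatch(
    scenario_spec(window, case_model, control_model, n_case, n_control),
    error = function(e) fail("scenario", conditionMessage(e)))

  structure(list(window = window, scenario = scenario,
                 grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
                 n_iter = as.integer(n_iter), alpha = alpha, tails = tails,
                 threshold = threshold, seed = as.integer(raw$seed),
                 edge_correct = edge_correct,
                 sweep = raw$sweep, raw = raw),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

window_from_config <- function(w, dir, fail) {
  if (inherits(w, "study_window")) return(w)
  if (is.null(w$type)) fail("window.type", "missing")
  switch(w$type,
    disc = {
      if (length(unlist(w$center)) != 2) fail("window.center", "needs [x, y]")
      if (is.null(w$radius) || w$radius <= 0) fail("window.radius", "must be > 0")
      disc_window(unlist(w$center), w$radius)
    },
    rectangle = {
      for (k in c("xmin", "ymin", "xmax", "ymax")) {
        if (is.null(w[[k]])) fail(paste0("window.", k), "missing")
      }
      rectangle_window(w$xmin, w$ymin, w$xmax, w$ymax)
    },
    geojson = {
      if (is.null(w$path)) fail("window.path", "missing")
      p <- if (file.exists(w$path)) w$path else file.path(dir, w$path)
      read_window_geojson(p)
    },
    fail("window.type", paste0("unknown type '", w$type, "'")))
}

model_from_config <- function(m, field, fail) {
  if (inherits(m, "group_model")) return(m)
  if (is.null(m$type)) fail(paste0(field, ".type"), "missing")
  switch(m$type,
    mvn = {
      centers <- m$centers %||% m$center
      if (is.null(centers)) fail(paste0(field, ".centers"), "missing")
      if (is.list(centers)) centers <- do.call(rbind, lapply(centers, unlist))
      if (is.null(m$sigma) || any(unlist(m$sigma) <= 0)) {
        fail(paste0(field, ".sigma"), "must be > 0")
      }
      mvn_model(centers, unlist(m$sigma), unlist(m$weights))
    },
    csr = csr_model(),
    uniform = {
      if (length(unlist(m$center)) != 2) fail(paste0(field, ".center"), "needs [x, y]")
      if (is.null(m$radius) || m$radius <= 0) fail(paste0(field, ".radius"), "must be > 0")
      uniform_model(unlist(m$center), m$radius)
    },
    fail(paste0(field, ".type"), paste0("unknown type '", m$type, "'")))
}

# serialize a power run back to a plain config list (the metadata sidecar)
config_from_run <- function(psurf) {
  sc <- psurf$scenario
  w <- sc$window
  wcfg <- switch(w$kind,
    disc = list(type = "disc", center = w$center, radius = w$radius),
    rectangle = list(type = "rectangle",
                     xmin = unname(w$bbox[["xmin"]]), ymin = unname(w$bbox[["ymin"]]),
                     xmax = unname(w$bbox[["xmax"]]), ymax = unname(w$bbox[["ymax"]])),
    list(type = "polygon", rings = lapply(w$rings, function(r) unname(r))))
  mcfg <- function(m) {
    switch(m$type,
      mvn = list(type = "mvn", centers = unname(m$centers), sigma = m$sigma,
                 weights = m$weights),
      csr = list(type = "csr"),
      uniform = list(type = "uniform", center = m$center, radius = m$radius))
  }
  list(window = wcfg, case_model = mcfg(sc$case_model),
       control_model = mcfg(sc$control_model),
       n_case = sc$n_case, n_control = sc$n_control,
       grid = list(nx = psurf$grid$nx, ny = psurf$grid$ny),
       n_iter = psurf$n_iter, alpha = psurf$alpha, tails = psurf$tails,
       threshold = psurf$threshold, seed = psurf$seed)
}

# rebuild a run_config from a metadata sidecar's config block
config_from_meta <- function(path) {
  meta <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  cfg <- meta$config
  if (identical(cfg$window$type, "polygon")) {
    cfg$window <- list(type = "polygon")  # not round-trippable via validate
    stop("polygon windows round-trip via GeoJSON, not the metadata sidecar",
         call. = FALSE)
  }
  validate_config(cfg, dir = dirname(path))
}

#' Run a power calculation from a configuration
#'
#' @param config A `run_config` from [read_config()]/[validate_config()].
#' @param verbose Progress logging.
#' @return A `power_surface`.
#' @export
run_power <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  grid <- make_grid(config$window, config$grid_nx, config$grid_ny)
  spatial_power(config$scenario, n_iter = config$n_iter, alpha = config$alpha,
                tails = config$tails, threshold = config$threshold,
                grid = grid, seed = config$seed,
                edge_correct = config$edge_correct, verbose = verbose)
}
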