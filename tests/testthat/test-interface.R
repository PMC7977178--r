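example_config <- function(name = "fort_dodge_n436.yaml") {
  system.file("extdata", name, package = "srrpower")
}

test_that("bundled configs parse with the documented study parameters", {
  cfg <- read_config(example_config())
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$scenario$n_case, 8L)
  expect_equal(cfg$scenario$n_control, 428L)
  expect_equal(cfg$scenario$case_model$sigma, 0.83)
  expect_equal(cfg$scenario$control_model$sigma, 1.67)
  expect_equal(cfg$window$radius, 10)
  expect_equal(c(cfg$grid_nx, cfg$grid_ny), c(128L, 128L))
  expect_equal(cfg$n_iter, 10000L)
  expect_equal(cfg$alpha, 0.05)
  expect_equal(cfg$tails, "two")
  expect_equal(cfg$threshold, 0.8)

  big <- read_config(example_config("fort_dodge_n1000.yaml"))
  expect_equal(big$scenario$n_case, 18L)
  expect_equal(big$scenario$n_control, 982L)

  sweep <- read_config(example_config("sweep_table_s1.yaml"))
  expect_equal(unlist(sweep$sweep$incidences), c(20.6, 917.45, 1834.9))
  expect_equal(unlist(sweep$sweep$n_totals), c(10000, 24000))
})

test_that("invalid configs fail with named fields before any simulation", {
  base <- yaml::read_yaml(example_config())
  broken <- list(
    list(key = "window", value = NULL, msg = "window"),
    list(key = "alpha", value = 2, msg = "alpha"),
    list(key = "threshold", value = 0, msg = "threshold"),
    list(key = "n_iter", value = 0, msg = "n_iter"),
    list(key = "seed", value = NULL, msg = "seed"),
    list(key = "tails", value = "both", msg = "tails"))
  for (b in broken) {
    raw <- base
    raw[[b$key]] <- b$value
    expect_error(validate_config(raw), b$msg)
  }
  raw <- base
  raw$n_total <- NULL; raw$incidence_per_100k <- NULL
  expect_error(validate_config(raw), "n_case")
  raw$n_case <- 0; raw$n_control <- 10
  expect_error(validate_config(raw), "n_case")
  raw <- base
  raw$case_model$sigma <- -1
  expect_error(validate_config(raw), "case_model.sigma")
})

test_that("config overrides replace file values", {
  cfg <- read_config(example_config(),
                     overrides = list(n_iter = 7, seed = 99,
                                      grid = list(nx = 16, ny = 16)))
  expect_equal(cfg$n_iter, 7L)
  expect_equal(cfg$seed, 99L)
  expect_equal(cfg$grid_nx, 16L)
})

test_that("ASCII grids round-trip to printed precision", {
  w <- disc_window(c(0, 0), 10)
  g <- make_grid(w, 20, 20)
  set.seed(71)
  surf <- kde_surface(simulate_csr(40, w), g, 1.5)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(surf$values, g, path)
  back <- read_ascii_grid(path)
  expect_equal(back$nx, 20)
  expect_equal(back$cellsize, g$xstep, tolerance = 1e-9)
  expect_equal(back$values, surf$values, tolerance = 1e-9)
  expect_identical(is.na(back$values), is.na(surf$values))
  # rectangular cells cannot be expressed in the format
  gr <- make_grid(rectangle_window(0, 0, 2, 1), 10, 10)
  expect_error(write_ascii_grid(matrix(0, 10, 10), gr, path), "square cells")
})

test_that("power surfaces write rasters plus a re-runnable metadata sidecar", {
  cfg <- read_config(example_config(),
                     overrides = list(n_iter = 12, seed = 5,
                                      grid = list(nx = 16, ny = 16)))
  ps <- run_power(cfg, verbose = FALSE)
  dir <- withr::local_tempdir()
  paths <- write_power_surface(ps, dir)
  expect_true(all(file.exists(paths)))
  back <- read_ascii_grid(paths[["power"]])
  expect_equal(back$values[ps$n_eval > 0], ps$power[ps$n_eval > 0],
               tolerance = 1e-9)
  # the sidecar config reproduces the identical surface
  cfg2 <- srrpower:::config_from_meta(paths[["meta"]])
  ps2 <- run_power(cfg2, verbose = FALSE)
  expect_identical(ps$power, ps2$power)
  expect_identical(ps$n_reject, ps2$n_reject)
})

test_that("cli_simulate writes the labelled CSV deterministically", {
  cfg <- read_config(example_config(), overrides = list(seed = 3))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  suppressMessages(cli_simulate(cfg, d1))
  suppressMessages(cli_simulate(cfg, d2))
  f1 <- file.path(d1, "points.csv")
  df <- utils::read.csv(f1)
  expect_equal(nrow(df), 436)
  expect_equal(sum(df$group == "case"), 8)
  expect_identical(readLines(f1), readLines(file.path(d2, "points.csv")))
})

test_that("cli_power summary agrees with the written rasters", {
  cfg <- read_config(example_config(),
                     overrides = list(n_iter = 30, seed = 11,
                                      grid = list(nx = 16, ny = 16),
                                      case_model = list(type = "mvn",
                                                        centers = list(c(0, 0)),
                                                        sigma = 1.67)))
  d <- withr::local_tempdir()
  msgs <- capture.output(paths <- cli_power(cfg, d, verbose = FALSE),
                         type = "message")
  expect_true(any(grepl("powered region", msgs)))
  meta <- jsonlite::fromJSON(paths[["meta"]])
  pow <- read_ascii_grid(paths[["power"]])$values
  mask <- read_ascii_grid(paths[["powered"]])$values
  expect_equal(meta$powered$n_knots, sum(mask == 1, na.rm = TRUE))
  expect_equal(sum(pow >= cfg$threshold & !is.na(pow)),
               meta$powered$n_knots)
})

test_that("the command-line script runs end-to-end and fails loudly", {
  script <- system.file("cli", "srrpower", package = "srrpower")
  rscript <- file.path(R.home("bin"), "Rscript")
  d <- withr::local_tempdir()
  cfg <- example_config()
  out <- system2(rscript, c(script, "simulate", "--config", shQuote(cfg),
                            "--out", shQuote(d), "--seed", "2"),
                 stdout = TRUE, stderr = TRUE)
  expect_equal(attr(out, "status"), NULL)  # exit 0
  expect_true(file.exists(file.path(d, "points.csv")))
  # missing window file -> non-zero exit and a clear error
  bad <- suppressWarnings(
    system2(rscript, c(script, "power", "--config", "missing.yaml"),
            stdout = TRUE, stderr = TRUE))
  expect_equal(attr(bad, "status"), 1L)
  expect_true(any(grepl("not found", bad)))
  # unknown subcommand -> usage and exit 2
  usage <- suppressWarnings(
    system2(rscript, c(script, "frobnicate"), stdout = TRUE, stderr = TRUE))
  expect_equal(attr(usage, "status"), 2L)
})

test_that("plots encode the field conventions", {
  cfg <- read_config(example_config(), overrides = list(seed = 3))
  pat <- simulate_scenario(cfg$scenario, seed = 3)
  p <- plot_pattern(pat, source = c(0, 0))
  built <- ggplot2::ggplot_build(p)
  pts <- built$data[[2]]
  expect_equal(sum(pts$colour == "red"), 8)      # cases
  expect_equal(sum(pts$colour == "blue"), 428)   # controls
  ps <- run_power(read_config(example_config(),
                              overrides = list(n_iter = 10, seed = 5,
                                               grid = list(nx = 12, ny = 12))),
                  verbose = FALSE)
  pp <- plot_power(ps, source = c(0, 0))
  bp <- ggplot2::ggplot_build(pp)
  # two-class fill scheme split at the threshold
  expect_true(all(bp$data[[1]]$fill %in% c("#2e8b57", "#4169e1")))
  png_path <- withr::local_tempfile(fileext = ".png")
  save_plot_png(pp, png_path, width = 3, height = 3, dpi = 72)
  expect_true(file.exists(png_path))
  expect_gt(file.size(png_path), 0)
})
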