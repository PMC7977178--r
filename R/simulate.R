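#' Group sampling models
#'
#' A sampling model describes how one group's locations are generated inside
#' the study window:
#'
#' * `mvn_model()` — one or more Gaussian clusters: each point is a center
#'   plus independent N(0, sigma) offsets per axis. With several clusters the
#'   group size is allocated across clusters proportionally to `weights`
#'   (largest-remainder rounding, equal weights by default).
#' * `csr_model()` — complete spatial randomness: points uniform over the
#'   whole window (a homogeneous Poisson process conditioned on n).
#' * `uniform_model()` — points uniform within a disc of given radius around
#'   a center (a flat-topped cluster), intersected with the window.
#'
#' Draws falling outside the window are rejected and redrawn so that every
#' returned point lies inside it; rejection preserves the shape of the
#' density inside the window, which is what the density ratio sees.
#'
#' @param centers Cluster center(s): length-2 vector or a matrix with one
#'   row per cluster.
#' @param sigma Per-axis standard deviation(s), recycled across clusters.
#' @param weights Positive allocation weights, recycled across clusters.
#' @param center,radius Center and radius of the uniform disc.
#' @return A model object consumed by [simulate_scenario()].
#' @export
mvn_model <- function(centers, sigma, weights = NULL) {
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 2, byrow = TRUE)
  centers <- as.matrix(centers)
  k <- nrow(centers)
  sigma <- rep_len(as.numeric(sigma), k)
  if (any(sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, k)
  weights <- rep_len(as.numeric(weights), k)
  if (any(weights <= 0)) stop("weights must be > 0", call. = FALSE)
  structure(list(type = "mvn", centers = centers, sigma = sigma,
                 weights = weights / sum(weights)),
            class = "group_model")
}

#' @rdname mvn_model
#' @export
csr_model <- function() {
  structure(list(type = "csr"), class = "group_model")
}

#' @rdname mvn_model
#' @export
uniform_model <- function(center, radius) {
  stopifnot(length(center) == 2, radius > 0)
  structure(list(type = "uniform", center = as.numeric(center),
                 radius = as.numeric(radius)),
            class = "group_model")
}

#' Scenario specification
#'
#' Bundles the study window, the case and control sampling models, and the
#' group sizes of one simulation scenario. Cluster centers must lie inside
#' the window; a power run requires at least one point in each group.
#'
#' @param window A [study_window].
#' @param case_model,control_model [group_model] objects (see [mvn_model]).
#' @param n_case,n_control Group sizes.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(window, case_model, control_model,
                          n_case, n_control) {
  stopifnot(inherits(window, "study_window"),
            inherits(case_model, "group_model"),
            inherits(control_model, "group_model"))
  n_case <- as.integer(n_case); n_control <- as.integer(n_control)
  if (n_case < 0 || n_control < 0) stop("group sizes must be >= 0", call. = FALSE)
  for (m in list(case_model, control_model)) {
    if (m$type == "mvn" && !all(contains(window, m$centers))) {
      stop("all cluster centers must lie inside the window", call. = FALSE)
    }
    if (m$type == "uniform" && !contains(window, m$center)) {
      stop("uniform-model center must lie inside the window", call. = FALSE)
    }
  }
  structure(list(window = window, case_model = case_model,
                 control_model = control_model,
                 n_case = n_case, n_control = n_control),
            class = "scenario_spec")
}

## ---- reproducible substreams -------------------------------------------

# One top-level seed expands into independent L'Ecuyer-CMRG substreams:
# stream 1 drives the (fixed) case pattern, stream 1 + t the controls of
# iteration t. This keeps the fixed-case / re-simulated-control protocol
# reproducible for any iteration count: extending a run never perturbs the
# earlier iterations.
make_streams <- function(seed, n) {
  old_kind <- RNGkind()
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

# evaluate expr with the RNG positioned at `stream`, restoring state after
with_stream <- function(stream, expr) {
  old_kind <- RNGkind()
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  assign(".Random.seed", stream, globalenv())
  expr
}

## ---- samplers (draw from the *current* RNG state) ----------------------

# rejection-sample `n` points from `propose(m)` until all lie in the window;
# expected redraws are capped at 1000 * n draws before erroring
rejection_sample <- function(n, window, propose, what) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  drawn <- 0L
  cap <- 1000 * n + 100
  while (got < n) {
    m <- max(n - got, 32L)
    if (drawn + m > cap) {
      stop("simulation infeasible: ", what,
           " places almost no mass inside the study window ",
           sprintf("(%d draws yielded %d points)", drawn, got), call. = FALSE)
    }
    p <- propose(m)
    drawn <- drawn + m
    keep <- which(contains(window, p))
    if (length(keep)) {
      take <- keep[seq_len(min(length(keep), n - got))]
      out[(got + 1L):(got + length(take)), ] <- p[take, , drop = FALSE]
      got <- got + length(take)
    }
  }
  out
}

#' Simulate one Gaussian cluster
#'
#' Draws `n` points as `center + N(0, sigma)` offsets per axis, rejecting
#' and redrawing any point that falls outside the window.
#'
#' @param n Number of points.
#' @param center Length-2 cluster center (inside the window).
#' @param sigma Per-axis standard deviation (> 0).
#' @param window A [study_window].
#' @return An n x 2 coordinate matrix. Uses the current RNG state; call
#'   `set.seed()` (or go through [simulate_scenario()]) for reproducibility.
#' @export
simulate_mvn_cluster <- function(n, center, sigma, window) {
  stopifnot(sigma > 0, n >= 0)
  rejection_sample(as.integer(n), window, function(m) {
    cbind(center[1] + stats::rnorm(m, 0, sigma),
          center[2] + stats::rnorm(m, 0, sigma))
  }, sprintf("MVN cluster at (%.3g, %.3g), sigma = %.3g",
             center[1], center[2], sigma))
}

#' Simulate complete spatial randomness
#'
#' `n` points uniformly distributed over the window (uniform proposals on
#' the bounding box, rejected to the window).
#'
#' @inheritParams simulate_mvn_cluster
#' @return An n x 2 coordinate matrix.
#' @export
simulate_csr <- function(n, window) {
  stopifnot(n >= 0)
  b <- window$bbox
  rejection_sample(as.integer(n), window, function(m) {
    cbind(stats::runif(m, b[["xmin"]], b[["xmax"]]),
          stats::runif(m, b[["ymin"]], b[["ymax"]]))
  }, "CSR over the window")
}

# uniform in a disc around center, clipped to the window by rejection
simulate_uniform_disc <- function(n, center, radius, window) {
  rejection_sample(as.integer(n), window, function(m) {
    r <- radius * sqrt(stats::runif(m))
    th <- stats::runif(m, 0, 2 * pi)
    cbind(center[1] + r * cos(th), center[2] + r * sin(th))
  }, sprintf("uniform disc at (%.3g, %.3g), radius %.3g",
             center[1], center[2], radius))
}

# largest-remainder allocation of n across weights (sums to n exactly)
allocate_counts <- function(n, weights) {
  raw <- n * weights
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  as.integer(base)
}

draw_group <- function(model, n, window) {
  switch(model$type,
    mvn = {
      counts <- allocate_counts(n, model$weights)
      do.call(rbind, lapply(seq_along(counts), function(k) {
        simulate_mvn_cluster(counts[k], model$centers[k, ], model$sigma[k],
                             window)
      }))
    },
    csr = simulate_csr(n, window),
    uniform = simulate_uniform_disc(n, model$center, model$radius, window),
    stop("unknown group model type: ", model$type, call. = FALSE))
}

#' Simulate a labelled case/control pattern
#'
#' Draws the case group and the control group from their respective models
#' and returns the combined labelled pattern. With a seed the draw is fully
#' reproducible; the cases use the same random substream as the first
#' iteration of [spatial_power()] with that seed, so the returned pattern is
#' exactly that run's first-iteration data.
#'
#' @param spec A [scenario_spec].
#' @param seed Integer seed (required for reproducibility; if `NULL` the
#'   current RNG state is used).
#' @return A [point_pattern] with `spec$n_case` cases and `spec$n_control`
#'   controls.
#' @export
simulate_scenario <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  draw <- function() {
    cases <- draw_group(spec$case_model, spec$n_case, spec$window)
    controls <- draw_group(spec$control_model, spec$n_control, spec$window)
    point_pattern(c(cases[, 1], controls[, 1]), c(cases[, 2], controls[, 2]),
                  rep(c("case", "control"), c(nrow(cases), nrow(controls))),
                  spec$window, check = FALSE)
  }
  if (is.null(seed)) return(draw())
  streams <- make_streams(seed, 2L)
  cases <- with_stream(streams[[1]],
                       draw_group(spec$case_model, spec$n_case, spec$window))
  controls <- with_stream(streams[[2]],
                          draw_group(spec$control_model, spec$n_control,
                                     spec$window))
  point_pattern(c(cases[, 1], controls[, 1]), c(cases[, 2], controls[, 2]),
                rep(c("case", "control"), c(nrow(cases), nrow(controls))),
                spec$window, check = FALSE)
}

#' Incidence arithmetic
#'
#' `split_by_incidence()` converts a total sample size and an incidence rate
#' (cases per 100,000 population) into case/control counts, rounding the
#' expected case count half-up; `incidence_per_100k()` is the inverse rate
#' computation.
#'
#' @param n_total Total sample size.
#' @param incidence_per_100k Incidence rate per 100,000.
#' @return `split_by_incidence`: named integer vector `c(n_case, n_control)`
#'   summing to `n_total`; `incidence_per_100k`: the rate per 100,000.
#' @examples
#' split_by_incidence(436, 1834.9)   # 8 cases, 428 controls
#' incidence_per_100k(8, 436)        # 1834.862...
#' @export
split_by_incidence <- function(n_total, incidence_per_100k) {
  stopifnot(n_total >= 0, incidence_per_100k >= 0,
            incidence_per_100k <= 1e5)
  # half-up rounding (round() would round half-to-even)
  n_case <- floor(n_total * incidence_per_100k / 1e5 + 0.5)
  c(n_case = as.integer(n_case), n_control = as.integer(n_total - n_case))
}

#' @rdname split_by_incidence
#' @param n_case Number of cases (at most `n_total`).
#' @export
incidence_per_100k <- function(n_case, n_total) {
  if (n_total < 1) stop("n_total must be >= 1", call. = FALSE)
  stopifnot(n_case >= 0, n_case <= n_total)
  1e5 * n_case / n_total
}
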