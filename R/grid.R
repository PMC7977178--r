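#' Evaluation grid of knots
#'
#' Builds the lattice of knots (grid-cell centers) over the bounding box of a
#' study window, together with the mask of knots whose centers fall inside
#' the window. All densities, risk statistics and power values are evaluated
#' at these knots; knots outside the window are excluded from every
#' downstream statistic.
#'
#' The grid also carries the quadrature weights used by the kernel
#' edge-correction integral: a subgrid `quad_factor` times finer than the
#' knot lattice, each fine cell weighted by the fraction of its area inside
#' the window (estimated from a `quad_subsample` x `quad_subsample` point
#' sample per fine cell).
#'
#' @param window A [study_window].
#' @param nx,ny Number of knots per axis (default 128, the conventional
#'   resolution for spatial relative risk surfaces).
#' @param quad_factor Refinement factor of the edge-correction subgrid
#'   relative to the knot lattice.
#' @param quad_subsample Per-fine-cell subsampling order for the inside-area
#'   fraction.
#' @return An object of class `srr_grid`: `window`, `nx`, `ny`, knot center
#'   coordinates `x` (length `nx`) and `y` (length `ny`), steps `xstep`,
#'   `ystep`, `cell_area`, logical `inside` matrix (`nx` x `ny`, knot
#'   `[i, j]` at `(x[i], y[j])`), and quadrature nodes/weights `qx`, `qy`,
#'   `qw`.
#' @examples
#' g <- make_grid(rectangle_window(0, 0, 1, 1), nx = 16, ny = 16)
#' sum(g$inside)  # 256: a rectangle contains its whole interior lattice
#' @export
make_grid <- function(window, nx = 128L, ny = 128L,
                      quad_factor = 4L, quad_subsample = 4L) {
  stopifnot(inherits(window, "study_window"))
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 2L || ny < 2L) stop("nx and ny must both be >= 2", call. = FALSE)
  b <- window$bbox
  xstep <- (b["xmax"] - b["xmin"]) / nx
  ystep <- (b["ymax"] - b["ymin"]) / ny
  x <- b[["xmin"]] + (seq_len(nx) - 0.5) * xstep
  y <- b[["ymin"]] + (seq_len(ny) - 0.5) * ystep
  pts <- cbind(rep(x, times = ny), rep(y, each = nx))
  inside <- matrix(contains(window, pts), nrow = nx, ncol = ny)

  fx <- nx * quad_factor; fy <- ny * quad_factor
  qxs <- (b[["xmax"]] - b[["xmin"]]) / fx
  qys <- (b[["ymax"]] - b[["ymin"]]) / fy
  qx <- b[["xmin"]] + (seq_len(fx) - 0.5) * qxs
  qy <- b[["ymin"]] + (seq_len(fy) - 0.5) * qys
  qw <- inside_fraction(window, qx, qy, qxs, qys, quad_subsample) * qxs * qys

  structure(list(window = window, nx = nx, ny = ny, x = x, y = y,
                 xstep = unname(xstep), ystep = unname(ystep),
                 cell_area = unname(xstep * ystep), inside = inside,
                 qx = qx, qy = qy, qw = qw),
            class = "srr_grid")
}

# fraction of each fine cell inside the window, midpoint subsampling
inside_fraction <- function(window, qx, qy, qxs, qys, s) {
  fx <- length(qx); fy <- length(qy)
  frac <- matrix(0, fx, fy)
  off_x <- ((seq_len(s) - 0.5) / s - 0.5) * qxs
  off_y <- ((seq_len(s) - 0.5) / s - 0.5) * qys
  for (ox in off_x) {
    for (oy in off_y) {
      pts <- cbind(rep(qx + ox, times = fy), rep(qy + oy, each = fx))
      frac <- frac + matrix(contains(window, pts), fx, fy)
    }
  }
  frac / (s * s)
}

#' @export
print.srr_grid <- function(x, ...) {
  cat(sprintf("srr_grid: %d x %d knots (%d inside window), cell area %.6g\n",
              x$nx, x$ny, sum(x$inside), x$cell_area))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$x, b$x)) && isTRUE(all.equal(a$y, b$y)) &&
    identical(dim(a$inside), dim(b$inside))
}
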