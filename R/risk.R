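#' Log spatial relative risk surface
#'
#' The spatial relative risk function compares the spatial densities of two
#' labelled point groups, \eqn{r(z) = f(z)/g(z)} with \eqn{f} the case and
#' \eqn{g} the control density, and is analysed on the log scale,
#' \eqn{\rho(z) = \log f(z) - \log g(z)}. Under the null of no spatial
#' clustering of one group relative to the other, \eqn{\rho(z) = 0}
#' everywhere.
#'
#' A knot is *evaluable* when both density estimates exceed a numeric floor
#' (`1e-12` times the surface's window-mean density): where either density
#' collapses to zero the log-ratio and its asymptotic variance diverge, so
#' such knots are excluded from testing and from power, mirroring the usual
#' practice of reporting the risk surface only where both groups have
#' support.
#'
#' @param f,g `density_surface` objects for cases and controls, on the same
#'   grid with the same bandwidth.
#' @return An object of class `risk_surface`: `grid`, `rho`, `evaluable`
#'   (logical matrix), `h`, `n_case`, `n_control`, with `se`, `zscore`,
#'   `pvalue` filled by [asymptotic_test()].
#' @seealso [srr_risk()] for the one-call pipeline.
#' @export
log_relative_risk <- function(f, g) {
  stopifnot(inherits(f, "density_surface"), inherits(g, "density_surface"))
  if (!same_grid(f$grid, g$grid)) {
    stop("grid mismatch: f and g must share the same grid", call. = FALSE)
  }
  if (!isTRUE(all.equal(f$h, g$h))) {
    stop("bandwidth mismatch: f and g must share the same bandwidth",
         call. = FALSE)
  }
  grid <- f$grid
  eval_knots <- grid$inside &
    f$values > density_floor(f) & g$values > density_floor(g)
  eval_knots[is.na(eval_knots)] <- FALSE
  rho <- matrix(NA_real_, grid$nx, grid$ny)
  rho[eval_knots] <- log(f$values[eval_knots]) - log(g$values[eval_knots])
  structure(list(grid = grid, rho = rho, evaluable = eval_knots,
                 se = NULL, zscore = NULL, pvalue = NULL,
                 h = f$h, n_case = f$n_points, n_control = g$n_points),
            class = "risk_surface")
}

# evaluability floor: 1e-12 x the mean density over inside knots
density_floor <- function(surface) {
  1e-12 * mean(surface$values[surface$grid$inside])
}

#' Asymptotic normal knot test of the log relative risk
#'
#' Per-knot hypothesis test of \eqn{H_0: \rho(z) = 0} against
#' \eqn{H_A: \rho(z) \ne 0} using the asymptotic normality of the kernel
#' log-risk estimator. The plug-in standard error at an evaluable knot is
#' \deqn{\widehat{se}(z) = \sqrt{\frac{R(K)}{h^2}\left(\frac{1}{n_1 \hat f(z)}
#'   + \frac{1}{n_2 \hat g(z)}\right)},}
#' with \eqn{R(K) = \int K^2 = 1/(4\pi)} for the bivariate Gaussian kernel,
#' giving `zscore = rho / se` and the two-tailed normal p-value
#' \eqn{2(1 - \Phi(|z|))}. The observed (edge-corrected) densities enter the
#' variance as-is.
#'
#' @param risk A `risk_surface` from [log_relative_risk()].
#' @param f,g The case and control `density_surface`s used to build `risk`.
#' @return The `risk_surface` with `se`, `zscore`, `pvalue` filled.
#' @export
asymptotic_test <- function(risk, f, g) {
  stopifnot(inherits(risk, "risk_surface"))
  if (is.null(risk$rho)) stop("rho must be computed first", call. = FALSE)
  if (!same_grid(risk$grid, f$grid) || !same_grid(risk$grid, g$grid)) {
    stop("grid mismatch between risk and density surfaces", call. = FALSE)
  }
  RK <- 1 / (4 * pi)
  ev <- risk$evaluable
  se <- zs <- pv <- matrix(NA_real_, risk$grid$nx, risk$grid$ny)
  se[ev] <- sqrt(RK / risk$h^2 *
                   (1 / (f$n_points * f$values[ev]) +
                    1 / (g$n_points * g$values[ev])))
  zs[ev] <- risk$rho[ev] / se[ev]
  pv[ev] <- 2 * stats::pnorm(-abs(zs[ev]))
  risk$se <- se; risk$zscore <- zs; risk$pvalue <- pv
  risk
}

#' Knot-wise significance classification
#'
#' Classifies each evaluable knot as a rejection of the no-clustering null
#' at level `alpha` (strict inequality, `p < alpha`). `tails = "two"` uses
#' the two-tailed p-value; `"upper"` rejects only for case excess
#' (`zscore > 0` with one-sided p < alpha), `"lower"` only for case deficit.
#' Non-evaluable knots are never rejections.
#'
#' @param risk A tested `risk_surface` (see [asymptotic_test()]).
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param tails One of `"two"`, `"upper"`, `"lower"`.
#' @return A logical `nx` x `ny` matrix of rejections.
#' @export
classify_significant <- function(risk, alpha = 0.05,
                                 tails = c("two", "upper", "lower")) {
  stopifnot(inherits(risk, "risk_surface"))
  tails <- match.arg(tails)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (is.null(risk$pvalue)) {
    stop("p-values missing: run asymptotic_test() first", call. = FALSE)
  }
  rej <- matrix(FALSE, risk$grid$nx, risk$grid$ny)
  ev <- risk$evaluable
  p1 <- stats::pnorm(-risk$zscore[ev])  # one-sided upper p
  rej[ev] <- switch(tails,
    two   = risk$pvalue[ev] < alpha,
    upper = risk$zscore[ev] > 0 & p1 < alpha,
    lower = risk$zscore[ev] < 0 & (1 - p1) < alpha)
  rej[is.na(rej)] <- FALSE
  rej
}

#' Full risk-surface pipeline
#'
#' Convenience wrapper: pooled oversmoothing bandwidth (unless `h` is
#' given), edge-corrected case and control densities, log relative risk and
#' the asymptotic knot test, in one call.
#'
#' @param pattern A labelled [point_pattern] with both groups present.
#' @param grid An [make_grid()] grid on the pattern's window.
#' @param h Bandwidth; default is [os_bandwidth()] of the pooled pattern.
#' @param edge_correct Apply edge correction to both densities.
#' @return A tested `risk_surface`.
#' @export
srr_risk <- function(pattern, grid, h = NULL, edge_correct = TRUE) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (n_case(pattern) < 1L || n_control(pattern) < 1L) {
    stop("pattern must contain at least one case and one control",
         call. = FALSE)
  }
  if (is.null(h)) h <- os_bandwidth(pattern)
  f <- kde_surface(group_coords(pattern, "case"), grid, h, edge_correct)
  g <- kde_surface(group_coords(pattern, "control"), grid, h, edge_correct)
  asymptotic_test(log_relative_risk(f, g), f, g)
}

#' @export
print.risk_surface <- function(x, ...) {
  cat(sprintf(
    "risk_surface: %d/%d evaluable knots, h = %.4g, n = %d cases / %d controls%s\n",
    sum(x$evaluable), sum(x$grid$inside), x$h, x$n_case, x$n_control,
    if (is.null(x$pvalue)) " (untested)" else ""))
  invisible(x)
}
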