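#' Labelled point patterns
#'
#' A point pattern is a set of planar locations, each labelled `case` or
#' `control`, confined to a study window. Patterns are the input to the
#' density and risk estimators; simulated patterns are produced by
#' [simulate_scenario()] and friends.
#'
#' @param x,y Numeric coordinate vectors of equal length.
#' @param group Character/factor vector of labels in `{case, control}`,
#'   recycled if length 1.
#' @param window The [study_window] the points belong to.
#' @param check Verify that every point lies inside the window (default TRUE).
#' @return An object of class `point_pattern`: a data frame with columns
#'   `x`, `y`, `group` and attribute `window`.
#' @export
point_pattern <- function(x, y, group, window, check = TRUE) {
  stopifnot(length(x) == length(y), inherits(window, "study_window"))
  if (length(group) == 1L) group <- rep(group, length(x))
  stopifnot(length(group) == length(x))
  group <- factor(as.character(group), levels = c("case", "control"))
  if (anyNA(group)) stop("group labels must be 'case' or 'control'", call. = FALSE)
  if (check && length(x) && !all(contains(window, cbind(x, y)))) {
    stop("all points must lie inside the study window", call. = FALSE)
  }
  structure(data.frame(x = as.numeric(x), y = as.numeric(y), group = group),
            window = window, class = c("point_pattern", "data.frame"))
}

#' @rdname point_pattern
#' @param pattern A `point_pattern`.
#' @export
n_case <- function(pattern) sum(pattern$group == "case")

#' @rdname point_pattern
#' @export
n_control <- function(pattern) sum(pattern$group == "control")

#' @rdname point_pattern
#' @export
pattern_window <- function(pattern) attr(pattern, "window")

# coordinates of one group as a matrix
group_coords <- function(pattern, group) {
  as.matrix(pattern[pattern$group == group, c("x", "y")])
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point_pattern: %d points (%d case, %d control)\n",
              nrow(x), n_case(x), n_control(x)))
  invisible(x)
}

#' Read/write point patterns as CSV
#'
#' The on-disk format is a plain CSV with header `x,y,group` and
#' `group` in `{case, control}`.
#'
#' @param pattern A [point_pattern].
#' @param path File path.
#' @param window Window to attach on read; points are checked against it.
#' @export
write_pattern_csv <- function(pattern, path) {
  df <- as.data.frame(pattern)[, c("x", "y", "group")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pattern_csv
#' @export
read_pattern_csv <- function(path, window) {
  if (!file.exists(path)) stop("pattern file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "group")
  if (!all(need %in% names(df))) {
    stop("pattern CSV must have columns x,y,group", call. = FALSE)
  }
  point_pattern(df$x, df$y, df$group, window)
}
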