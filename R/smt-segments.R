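#' Summary statistics of an unwrapped trajectory segment
#'
#' Fits an ordinary least-squares line to position versus time and
#' reports the observable set used to classify directional motion:
#' `v` the slope (nm/s), `d` the total fitted displacement (nm), `l` the
#' segment length (both frames and seconds), `r` the standard deviation
#' of the residuals (nm), and the noise-to-signal ratio `R = r / d`.
#' Segments whose displacement is below 1 nm get `R = Inf` (stationary by
#' construction).
#'
#' @param t Time samples, s.
#' @param arc Positions along the unwrapped septum, nm.
#' @param min_points Minimum number of samples (default 4); fewer is an
#'   error.
#' @return A one-row tibble of class `smt_segment`: `v`, `d`, `l_frames`,
#'   `l_seconds`, `r`, `R`.
#' @examples
#' segment_statistics(0:9, 25 * (0:9)) # perfect 25 nm/s line: r = 0
#' @export
segment_statistics <- function(t, arc, min_points = 4) {
  stopifnot(length(t) == length(arc))
  if (length(t) < min_points) {
    stop("segment has fewer than ", min_points, " points")
  }
  fit <- stats::lm(arc ~ t)
  v <- unname(stats::coef(fit)[2])
  fitted <- unname(stats::fitted(fit))
  d <- abs(fitted[length(fitted)] - fitted[1])
  r <- stats::sd(stats::residuals(fit))
  R <- if (d < 1) Inf else unname(r / d)
  tibble::tibble(v = v, d = d, l_frames = length(t),
                 l_seconds = t[length(t)] - t[1], r = r, R = R)
}

#' Classify trajectory segments as processive or stationary
#'
#' Applies [segment_statistics()] to each user-delimited (or
#' automatically split, see [split_segments()]) piece of an unwrapped
#' trajectory and labels it `"processive"` when the noise-to-signal
#' statistic satisfies `R <= r_threshold` and the segment is long enough.
#'
#' @param unwrapped A tibble from [unwrap_trajectory()] (columns `t`,
#'   `arc`), or any data frame with those columns.
#' @param breakpoints Optional increasing vector of times at which to cut
#'   the trajectory into segments; by default the whole trajectory is one
#'   segment.
#' @param r_threshold Processive classification threshold on `R`
#'   (default 0.4).
#' @param min_points Minimum samples per segment (default 4); shorter
#'   segments are excluded.
#' @param min_duration Minimum segment duration in seconds (default 4).
#' @return A tibble with one row per retained segment: segment index,
#'   `t_start`, `t_end`, the [segment_statistics()] columns, `speed`
#'   (absolute `v`), `duration`, `distance`, and `label`.
#' @export
classify_segments <- function(unwrapped, breakpoints = NULL,
                              r_threshold = 0.4, min_points = 4,
                              min_duration = 4) {
  stopifnot(all(c("t", "arc") %in% names(unwrapped)))
  t <- unwrapped$t; arc <- unwrapped$arc
  cuts <- sort(unique(breakpoints))
  grp <- findInterval(t, cuts) + 1
  pieces <- split(seq_along(t), grp)
  rows <- lapply(seq_along(pieces), function(i) {
    idx <- pieces[[i]]
    if (length(idx) < min_points) return(NULL)
    if (t[idx[length(idx)]] - t[idx[1]] < min_duration) return(NULL)
    st <- segment_statistics(t[idx], arc[idx], min_points)
    dplyr::mutate(st,
                  segment = i, t_start = t[idx[1]],
                  t_end = t[idx[length(idx)]],
                  speed = abs(.data$v),
                  duration = .data$t_end - .data$t_start,
                  distance = .data$d,
                  label = ifelse(.data$R <= r_threshold,
                                 "processive", "stationary"),
                  .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' Automatic changepoint splitting of an unwrapped trajectory
#'
#' Greedy binary segmentation with a piecewise-linear fit: the trajectory
#' is recursively split at the time that most reduces the residual sum of
#' squares, while the reduction exceeds `penalty` times the residual
#' variance. This is an automation aid — segment boundaries in the
#' original analysis were drawn by eye — and is labelled as such.
#'
#' @param unwrapped A tibble with `t` and `arc`.
#' @param min_points Minimum samples per resulting segment.
#' @param penalty Split acceptance penalty (larger = fewer splits).
#' @return A numeric vector of breakpoint times (possibly empty).
#' @export
split_segments <- function(unwrapped, min_points = 4, penalty = 10) {
  t <- unwrapped$t; arc <- unwrapped$arc
  rss <- function(idx) {
    if (length(idx) < 2) return(0)
    sum(stats::residuals(stats::lm(arc[idx] ~ t[idx]))^2)
  }
  split_one <- function(idx) {
    n <- length(idx)
    if (n < 2 * min_points) return(NULL)
    base <- rss(idx)
    sig2 <- base / max(n - 2, 1)
    best_gain <- -Inf; best_k <- NULL
    for (k in min_points:(n - min_points)) {
      gain <- base - rss(idx[1:k]) - rss(idx[(k + 1):n])
      if (gain > best_gain) { best_gain <- gain; best_k <- k }
    }
    if (!is.null(best_k) && best_gain > penalty * sig2) best_k else NULL
  }
  out <- numeric(0)
  recurse <- function(idx) {
    k <- split_one(idx)
    if (is.null(k)) return(invisible())
    out <<- c(out, (t[idx[k]] + t[idx[k + 1]]) / 2)
    recurse(idx[1:k])
    recurse(idx[(k + 1):length(idx)])
  }
  recurse(seq_along(t))
  sort(out)
}
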