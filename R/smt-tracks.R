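#' Read and filter single-molecule localization tables
#'
#' Localization tables are delimited text with named columns `frame`,
#' `x`, `y` (nm), `intensity`, `sigma` (nm) and optionally `uncertainty`
#' (nm) — the column set produced by standard localization software.
#'
#' @param path Delimited text file (comma or whitespace separated, header
#'   row).
#' @return A tibble, one row per localization.
#' @export
read_localizations <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("frame", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  tibble::as_tibble(df)
}

#' @rdname read_localizations
#' @param locs A localization tibble.
#' @export
write_localizations <- function(locs, path) {
  utils::write.csv(locs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Quality-filter localizations by intensity and PSF width
#'
#' Rows with intensity below `min_intensity` or fitted PSF sigma outside
#' `sigma_band` are removed (the standard post-processing gate for
#' camera-based localization data).
#'
#' @param locs A localization tibble with `intensity` and `sigma` columns.
#' @param min_intensity Minimum intensity (photons/ADU), default 300.
#' @param sigma_band Inclusive PSF sigma band, nm, default `c(60, 300)`.
#' @return The filtered tibble.
#' @examples
#' locs <- tibble::tibble(frame = 1:3, x = 0, y = 0,
#'                        intensity = c(299, 500, 500),
#'                        sigma = c(100, 100, 400))
#' filter_localizations(locs) # keeps only row 2
#' @export
filter_localizations <- function(locs, min_intensity = 300,
                                 sigma_band = c(60, 300)) {
  need <- c("intensity", "sigma")
  miss <- setdiff(need, names(locs))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  dplyr::filter(locs,
                .data$intensity >= min_intensity,
                .data$sigma >= sigma_band[1],
                .data$sigma <= sigma_band[2])
}

#' Link localizations into trajectories
#'
#' Greedy mutual-nearest-neighbour linking between frames: a localization
#' is appended to the track whose last position is nearest, provided the
#' displacement is below `max_disp` and the dark gap does not exceed
#' `max_gap` frames; otherwise it seeds a new track. No two tracks share
#' a localization.
#'
#' @param locs A localization tibble sorted by `frame`.
#' @param max_disp Maximum displacement per link, nm (default 300, which
#'   at 1 s/frame corresponds to ~0.05 um^2/s or a top speed of 300 nm/s).
#' @param max_gap Maximum number of missed frames across which a link is
#'   still allowed (default 15).
#' @return The input tibble with a `track` integer column, sorted by
#'   track then frame.
#' @export
link_localizations <- function(locs, max_disp = 300, max_gap = 15) {
  locs <- dplyr::arrange(locs, .data$frame)
  n <- nrow(locs)
  track <- integer(n)
  if (!n) return(dplyr::mutate(locs, track = integer(0)))
  # open track state: last position and frame per live track
  last_x <- numeric(0); last_y <- numeric(0)
  last_f <- numeric(0); ids <- integer(0)
  next_id <- 1L
  for (fr in unique(locs$frame)) {
    rows <- which(locs$frame == fr)
    live <- which(fr - last_f <= max_gap + 1 & last_f < fr)
    # distance matrix candidates -> greedy best-pair assignment
    if (length(live) && length(rows)) {
      dmat <- outer(seq_along(rows), seq_along(live),
                    function(i, j) {
                      sqrt((locs$x[rows[i]] - last_x[live[j]])^2 +
                             (locs$y[rows[i]] - last_y[live[j]])^2)
                    })
      dmat[dmat > max_disp] <- NA
      taken_r <- rep(FALSE, length(rows))
      taken_l <- rep(FALSE, length(live))
      repeat {
        if (all(is.na(dmat))) break
        best <- arrayInd(which.min(dmat), dim(dmat))
        i <- best[1]; j <- best[2]
        r <- rows[i]; l <- live[j]
        track[r] <- ids[l]
        last_x[l] <- locs$x[r]; last_y[l] <- locs$y[r]; last_f[l] <- fr
        taken_r[i] <- TRUE; taken_l[j] <- TRUE
        dmat[i, ] <- NA; dmat[, j] <- NA
      }
      new_rows <- rows[!taken_r]
    } else {
      new_rows <- rows
    }
    for (r in new_rows) {
      track[r] <- next_id
      last_x <- c(last_x, locs$x[r]); last_y <- c(last_y, locs$y[r])
      last_f <- c(last_f, fr); ids <- c(ids, next_id)
      next_id <- next_id + 1L
    }
  }
  dplyr::arrange(dplyr::mutate(locs, track = track),
                 .data$track, .data$frame)
}
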