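#' Specification for synthetic septal-ring tracking data
#'
#' Emulates single-molecule acquisitions of enzymes moving on the
#' division septum of a vertically trapped cell: a circle of ~1.2--1.4 um
#' diameter imaged at 1 s/frame with Gaussian localization noise.
#'
#' @param diameter Ring diameter, nm (default 1300).
#' @param mode `"directional"` (constant arc speed), `"diffusive"`
#'   (Brownian motion along the arc), or `"switching"` (directional with
#'   occasional pauses).
#' @param speed Arc speed for directional motion, nm/s.
#' @param D Diffusion constant for diffusive motion, um^2/s.
#' @param frame_interval Seconds per frame (default 1).
#' @param n_frames Number of frames.
#' @param noise_sd Localization noise SD per axis, nm (default 20).
#' @param drop_prob Probability that a frame is dropped (dark frame).
#' @param intensity_mean Mean localization intensity (ADU).
#' @param sigma_mean Mean fitted PSF sigma, nm.
#' @return A `ring_track_spec` list.
#' @export
ring_track_spec <- function(diameter = 1300,
                            mode = c("directional", "diffusive",
                                     "switching"),
                            speed = 25, D = 0.01, frame_interval = 1,
                            n_frames = 60, noise_sd = 20, drop_prob = 0,
                            intensity_mean = 1000, sigma_mean = 150) {
  mode <- match.arg(mode)
  stopifnot(diameter > 0, noise_sd >= 0, n_frames >= 1,
            drop_prob >= 0, drop_prob < 1)
  structure(list(diameter = diameter, mode = mode, speed = speed, D = D,
                 frame_interval = frame_interval, n_frames = n_frames,
                 noise_sd = noise_sd, drop_prob = drop_prob,
                 intensity_mean = intensity_mean,
                 sigma_mean = sigma_mean),
            class = "ring_track_spec")
}

#' Generate localizations of a molecule moving on a septal ring
#'
#' A molecule moves along the circumference (directionally, diffusively,
#' or switching between run and pause states), is projected to 2D,
#' Gaussian localization noise is added, and frames may be dropped to
#' exercise gap closing. Deterministic under a fixed seed.
#'
#' @param spec A [ring_track_spec()].
#' @param seed Seed.
#' @return A localization tibble (`frame`, `x`, `y`, `intensity`,
#'   `sigma`, `uncertainty`) with attributes `true_arc` (noise-free arc
#'   positions for every frame) and `circle` (true ring geometry).
#' @export
generate_ring_localizations <- function(spec = ring_track_spec(),
                                        seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  r <- spec$diameter / 2
  dtf <- spec$frame_interval
  n <- spec$n_frames
  arc <- switch(spec$mode,
    directional = spec$speed * dtf * (seq_len(n) - 1),
    diffusive = cumsum(c(0, stats::rnorm(n - 1, 0,
                                         sqrt(2 * spec$D * 1e6 * dtf)))),
    switching = {
      # two-state run/pause with 0.1/s switching hazard
      state <- logical(n); state[1] <- TRUE
      for (i in 2:n) {
        state[i] <- if (stats::runif(1) < 0.1 * dtf) !state[i - 1] else
          state[i - 1]
      }
      cumsum(c(0, ifelse(state[-1], spec$speed * dtf, 0)))
    })
  theta <- arc / r
  x <- r * cos(theta) + stats::rnorm(n, 0, spec$noise_sd)
  y <- r * sin(theta) + stats::rnorm(n, 0, spec$noise_sd)
  keep <- stats::runif(n) >= spec$drop_prob
  keep[1] <- TRUE
  out <- tibble::tibble(
    frame = seq_len(n)[keep],
    x = x[keep], y = y[keep],
    intensity = stats::rpois(sum(keep), spec$intensity_mean),
    sigma = stats::rnorm(sum(keep), spec$sigma_mean, 10),
    uncertainty = rep(spec$noise_sd, sum(keep)))
  attr(out, "true_arc") <- tibble::tibble(frame = seq_len(n), arc = arc)
  attr(out, "circle") <- list(cx = 0, cy = 0, r = r)
  out
}

#' Generate speed samples from a two-component log-normal mixture
#'
#' @param P Slow-component weight in \[0, 1\].
#' @param mu1,sigma1 Log-scale parameters of the slow component.
#' @param mu2,sigma2 Log-scale parameters of the fast component.
#' @param n Number of samples.
#' @param seed Seed.
#' @return Speeds (nm/s) with attribute `component` (1 = slow, 2 = fast).
#' @examples
#' sp <- generate_speed_samples(0.4, log(8), 0.3, log(30), 0.4, n = 100)
#' @export
generate_speed_samples <- function(P, mu1, sigma1, mu2, sigma2, n,
                                   seed = 1L) {
  stopifnot(P >= 0, P <= 1, sigma1 > 0, sigma2 > 0, n >= 0)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (n == 0) return(numeric(0))
  comp <- ifelse(stats::runif(n) < P, 1L, 2L)
  out <- ifelse(comp == 1L,
                stats::rlnorm(n, mu1, sigma1),
                stats::rlnorm(n, mu2, sigma2))
  attr(out, "component") <- comp
  out
}

#' Generate 2D Brownian tracks with localization noise
#'
#' Per-axis increments have variance `2 D dt`; isotropic Gaussian
#' localization noise of SD `noise_sd` is added to every position
#' independently, producing the constant MSD offset
#' \eqn{D_0 = 4\,\mathrm{noise\_sd}^2}.
#'
#' @param D Diffusion constant, um^2/s (>= 0).
#' @param n_tracks Number of tracks.
#' @param n_frames Frames per track.
#' @param frame_interval Seconds per frame (default 0.03, fast-streaming
#'   acquisition).
#' @param noise_sd Localization noise SD per axis, nm.
#' @param seed Seed.
#' @return A tibble with `track`, `frame`, `t`, `x`, `y` (nm).
#' @export
generate_diffusive_tracks <- function(D, n_tracks = 50, n_frames = 30,
                                      frame_interval = 0.03,
                                      noise_sd = 20, seed = 1L) {
  stopifnot(D >= 0, n_tracks >= 1, n_frames >= 2)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sd_step <- sqrt(2 * D * 1e6 * frame_interval)
  purrr::map_dfr(seq_len(n_tracks), function(k) {
    x <- cumsum(c(0, stats::rnorm(n_frames - 1, 0, sd_step)))
    y <- cumsum(c(0, stats::rnorm(n_frames - 1, 0, sd_step)))
    tibble::tibble(
      track = k, frame = seq_len(n_frames),
      t = (seq_len(n_frames) - 1) * frame_interval,
      x = x + stats::rnorm(n_frames, 0, noise_sd),
      y = y + stats::rnorm(n_frames, 0, noise_sd))
  })
}
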