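#' Scenario specification for ratchet simulations
#'
#' @param init_mode Where the enzyme starts: `"at_shrinking_end"` (enzyme
#'   and shrinking end together at the left boundary), `"mid_filament"`
#'   (a uniformly random live subunit center), or `"at_growing_end"`.
#' @param n_enzymes Number of enzymes on the filament (>= 1).
#' @param track_end Which filament end the persistence criterion refers
#'   to. Defaults to the shrinking end; growing-end tracking is the
#'   negative-control scenario.
#' @return A `ratchet_scenario` list.
#' @export
ratchet_scenario <- function(init_mode = c("at_shrinking_end",
                                           "mid_filament",
                                           "at_growing_end"),
                             n_enzymes = 1L,
                             track_end = c("shrinking", "growing")) {
  init_mode <- match.arg(init_mode)
  track_end <- match.arg(track_end)
  stopifnot(n_enzymes >= 1)
  structure(list(init_mode = init_mode, n_enzymes = as.integer(n_enzymes),
                 track_end = track_end),
            class = "ratchet_scenario")
}

init_position <- function(scenario, params) {
  switch(scenario$init_mode,
    at_shrinking_end = 0,
    at_growing_end = (params$n_fil - 1) * params$L0,
    mid_filament = (sample.int(params$n_fil, 1) - 1) * params$L0)
}

#' Simulate one enzyme trajectory on a treadmilling filament
#'
#' Integrates the overdamped Langevin equation for the enzyme with the
#' explicit Euler--Maruyama scheme while the filament treadmills on a
#' deterministic clock (one subunit lost at the shrinking end and one
#' gained at the growing end every `L0/(v_z dt)` steps). Boundaries are
#' open; a trajectory ends at `t_max` or once the enzyme has stayed more
#' than `escape_margin` beyond either filament end for longer than
#' `escape_hold` seconds.
#'
#' @param params A [ratchet_params()] object.
#' @param scenario A [ratchet_scenario()]; default starts the enzyme at
#'   the shrinking end.
#' @param seed Integer seed for the trajectory's random-number stream.
#' @param stop_when `"termination"` records the full trajectory;
#'   `"persistent"` additionally stops as soon as the persistent
#'   end-tracking criterion of [classify_end_tracking()] is met (used for
#'   propensity screening); `"escape"` stops at the first instant the
#'   enzyme is beyond `escape_margin` of either end (bound-lifetime
#'   first-passage mode).
#' @param criteria An [end_track_criteria()] used by the `"persistent"`
#'   stop rule.
#' @param escape_margin,escape_hold Termination rule, nm and s.
#' @return A tibble of class `ratchet_trajectory` with columns `t`, `x`,
#'   `x_S`, `x_G`, `bound`, and attributes `params`, `scenario`, `seed`,
#'   `persistent`, `persistent_onset`, `escape_time`, `censored`.
#' @examples
#' traj <- simulate_trajectory(
#'   ratchet_params(D = 0.04, U0 = 10, v_z = 25, t_max = 10), seed = 1)
#' head(traj)
#' @export
simulate_trajectory <- function(params = ratchet_params(),
                                scenario = ratchet_scenario(),
                                seed = 1L,
                                stop_when = c("termination", "persistent",
                                              "escape"),
                                criteria = end_track_criteria(),
                                escape_margin = 100, escape_hold = 1) {
  stop_when <- match.arg(stop_when)
  check_stability(params)
  x0 <- init_position(scenario, params)
  stop_mode <- match(stop_when, c("termination", "persistent", "escape")) - 1L
  track_end <- if (scenario$track_end == "shrinking") 0L else 1L
  raw <- cpp_simulate(params$D_nm, params$U0, params$a, params$L0,
                      params$n_fil, params$v_z, params$dt, params$t_max,
                      x0, params$record_every, stop_mode, track_end,
                      criteria$max_gap, criteria$min_duration,
                      criteria$speed_fraction,
                      escape_margin, escape_hold, as.double(seed),
                      scheme_code(params))
  traj <- tibble::tibble(
    t = raw$t, x = raw$x, x_S = raw$x_S, x_G = raw$x_S + raw$span,
    bound = as.logical(raw$bound))
  structure(traj,
            class = c("ratchet_trajectory", class(traj)),
            params = params, scenario = scenario, seed = seed,
            persistent = raw$persistent,
            persistent_onset = raw$persistent_onset,
            escape_time = raw$escape_time,
            drop_times = raw$drop_times,
            censored = raw$censored)
}

#' Draw a treadmilling speed from a truncated Gaussian
#'
#' One Gaussian draw with mean `mean` and standard deviation `cv * mean`,
#' redrawn until positive. Measured in-vivo treadmilling speeds have a
#' roughly 30% coefficient of variation.
#'
#' @param mean Mean speed, nm/s (> 0).
#' @param cv Coefficient of variation in \[0, 1).
#' @param n Number of draws.
#' @return Speeds, nm/s.
#' @export
draw_treadmill_speed <- function(mean, cv = 0.3, n = 1) {
  stopifnot(mean > 0, cv >= 0, cv < 1)
  if (cv == 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, cv * mean)
      if (v > 0) break
    }
    out[i] <- v
  }
  out
}

#' Simulate an ensemble of independent trajectories
#'
#' Per-trajectory seeds are derived reproducibly from `seed`; two calls
#' with the same master seed are bit-identical. The treadmilling speed is
#' fixed within each trajectory; if `speed_dist` is given it is drawn per
#' trajectory from [draw_treadmill_speed()].
#'
#' @inheritParams simulate_trajectory
#' @param n_traj Number of trajectories (>= 1).
#' @param speed_dist Optional `list(mean =, cv =)` for across-ensemble
#'   treadmilling-speed variability.
#' @param seed Master seed.
#' @return A list of `ratchet_trajectory` tibbles, class
#'   `ratchet_ensemble`.
#' @export
simulate_ensemble <- function(params = ratchet_params(),
                              scenario = ratchet_scenario(),
                              n_traj = 100, speed_dist = NULL, seed = 1L,
                              stop_when = c("termination", "persistent",
                                            "escape"),
                              criteria = end_track_criteria(),
                              escape_margin = 100, escape_hold = 1) {
  stopifnot(n_traj >= 1)
  stop_when <- match.arg(stop_when)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_traj)
  speeds <- if (!is.null(speed_dist)) {
    draw_treadmill_speed(speed_dist$mean, speed_dist$cv, n_traj)
  }
  x0_seeds <- sample.int(.Machine$integer.max, n_traj)
  out <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    p_i <- params
    if (!is.null(speeds)) {
      p_i$v_z <- speeds[i]
      if (p_i$v_z > 0 && round(p_i$L0 / (p_i$v_z * p_i$dt)) < 1) {
        stop("drawn treadmilling speed too fast for dt in trajectory ", i)
      }
    }
    set.seed(x0_seeds[i]) # mid-filament initial-position draw
    out[[i]] <- tryCatch(
      simulate_trajectory(p_i, scenario, seed = seeds[i],
                          stop_when = stop_when, criteria = criteria,
                          escape_margin = escape_margin,
                          escape_hold = escape_hold),
      error = function(e) {
        stop("trajectory ", i, " failed: ", conditionMessage(e))
      })
  }
  structure(out, class = "ratchet_ensemble", params = params,
            scenario = scenario, seed = seed)
}

#' Bind an ensemble into one tall tibble
#'
#' @param ensemble A `ratchet_ensemble`.
#' @return A tibble with an added `traj` index column and per-trajectory
#'   `v_z` column.
#' @export
bind_ensemble <- function(ensemble) {
  purrr::map2_dfr(ensemble, seq_along(ensemble), function(tr, i) {
    dplyr::mutate(tibble::as_tibble(tr),
                  traj = i, v_z = attr(tr, "params")$v_z)
  })
}

#' Simulate several enzymes on one filament with hard-core exclusion
#'
#' Each enzyme follows the same Langevin dynamics; with
#' `exclusion = TRUE`, a proposed move landing within `excl_diameter` of
#' another enzyme is rejected, so enzymes cannot cross in 1D. Per-enzyme
#' bound lifetimes (first time beyond `escape_margin` of either filament
#' end) are returned as an attribute.
#'
#' @inheritParams simulate_trajectory
#' @param n_enzymes Number of enzymes (>= 2).
#' @param x0 Initial positions (nm); default places enzyme 1 at the
#'   shrinking end and the rest at evenly spaced interior subunits.
#' @param exclusion Apply the hard-core rule?
#' @param excl_diameter Exclusion diameter, nm (default one subunit).
#' @return A tall tibble (class `ratchet_multi_trajectory`) with columns
#'   `t`, `enzyme`, `x`, `x_S`, `x_G`; attribute `lifetimes` (s, NA when
#'   censored at `t_max`).
#' @export
simulate_multi_enzyme <- function(params = ratchet_params(),
                                  n_enzymes = 2, x0 = NULL,
                                  exclusion = TRUE,
                                  excl_diameter = NULL, seed = 1L,
                                  escape_margin = 100) {
  stopifnot(n_enzymes >= 2)
  check_stability(params)
  if (is.null(excl_diameter)) excl_diameter <- params$L0
  if (is.null(x0)) {
    idx <- unique(round(seq(0, params$n_fil - 1,
                            length.out = n_enzymes)))
    x0 <- idx * params$L0
  }
  stopifnot(length(x0) == n_enzymes)
  raw <- cpp_simulate_multi(params$D_nm, params$U0, params$a, params$L0,
                            params$n_fil, params$v_z, params$dt,
                            params$t_max, as.double(x0),
                            params$record_every, escape_margin,
                            exclusion, excl_diameter, as.double(seed),
                            scheme_code(params))
  n_rec <- length(raw$t)
  out <- tibble::tibble(
    t = rep(raw$t, n_enzymes),
    enzyme = rep(seq_len(n_enzymes), each = n_rec),
    x = unlist(raw$x),
    x_S = rep(raw$x_S, n_enzymes),
    x_G = rep(raw$x_S + raw$span, n_enzymes))
  structure(out, class = c("ratchet_multi_trajectory", class(out)),
            params = params, seed = seed, lifetimes = raw$lifetime)
}

scheme_code <- function(params) {
  if (identical(params$scheme, "euler")) 1L else 0L
}
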