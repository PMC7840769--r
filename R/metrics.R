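#' Criteria for persistent end-tracking
#'
#' A trajectory counts as persistent end-tracking when the enzyme stays
#' within `max_gap` of the tracked filament end continuously for at least
#' `min_duration` while genuinely following it. "Following" is scored by
#' three gates beyond the distance gate:
#' \itemize{
#'   \item a run terminates at a \emph{drop event}: a treadmilling event
#'     that fires while the enzyme has not caught up to within the tracked
#'     end's binding well (the event-wise mirror of the analytic stay-on /
#'     catch-up decomposition);
#'   \item net displacement over the qualifying window must reach at least
#'     `speed_fraction` of the distance the end itself travels (strictly
#'     positive when the filament does not treadmill);
#'   \item the enzyme must spend at least half of the window's samples
#'     inside the catch-up zone (within `L0 + a` of the end-subunit
#'     center) — an end-tracker rides the end well, whereas an enzyme
#'     merely parked on the filament or drifting inside the distance gate
#'     does not.
#' }
#'
#' @param max_gap Maximum enzyme-to-end distance, nm.
#' @param min_duration Minimum following time, s.
#' @param speed_fraction Minimum mean enzyme speed over the window as a
#'   fraction of the treadmilling speed.
#' @return An `end_track_criteria` list.
#' @export
end_track_criteria <- function(max_gap = 100, min_duration = 4,
                               speed_fraction = 0.5) {
  stopifnot(max_gap > 0, min_duration > 0,
            speed_fraction >= 0, speed_fraction < 1)
  structure(list(max_gap = max_gap, min_duration = min_duration,
                 speed_fraction = speed_fraction),
            class = "end_track_criteria")
}

#' Classify persistent end-tracking and extract run statistics
#'
#' Finds the maximal intervals of the recorded trajectory during which the
#' enzyme-to-end distance stays below `criteria$max_gap`, scores each
#' against the duration and follow tests of [end_track_criteria()], and
#' summarises every interval as a run with net speed, duration and
#' distance.
#'
#' @param traj A `ratchet_trajectory` (sampled at <= 0.05 s cadence).
#' @param criteria An [end_track_criteria()].
#' @param track_end `"shrinking"` or `"growing"`; defaults to the
#'   trajectory's scenario.
#' @return A list with `is_persistent` (logical) and `runs`, a tibble with
#'   one row per gap interval: `t_start`, `t_end`, `duration` (s),
#'   `distance` (net, nm), `speed` (nm/s), `persistent`.
#' @examples
#' traj <- simulate_trajectory(
#'   ratchet_params(D = 0.04, U0 = 10, v_z = 25, t_max = 15), seed = 2)
#' classify_end_tracking(traj)$is_persistent
#' @export
classify_end_tracking <- function(traj, criteria = end_track_criteria(),
                                  track_end = NULL) {
  if (is.null(track_end)) {
    sc <- attr(traj, "scenario")
    track_end <- if (is.null(sc)) "shrinking" else sc$track_end
  }
  ref <- if (track_end == "shrinking") traj$x_S else traj$x_G
  p <- attr(traj, "params")
  gap_ok <- abs(traj$x - ref) < criteria$max_gap
  # a drop event breaks the run at the first sample at or after it
  drops <- attr(traj, "drop_times")
  if (length(drops)) {
    idx <- findInterval(drops, traj$t) + 1
    gap_ok[idx[idx <= length(gap_ok)]] <- FALSE
  }
  runs <- gap_runs(traj$t, traj$x, abs(traj$x - ref), gap_ok,
                   p$v_z, p$L0 + p$a, criteria)
  list(is_persistent = any(runs$persistent), runs = runs)
}

gap_runs <- function(t, x, end_dist, gap_ok, v_z, catch_zone, criteria) {
  if (!any(gap_ok)) {
    return(tibble::tibble(t_start = numeric(), t_end = numeric(),
                          duration = numeric(), distance = numeric(),
                          speed = numeric(), ride_fraction = numeric(),
                          persistent = logical()))
  }
  rl <- rle(gap_ok)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1
  keep <- which(rl$values)
  out <- lapply(keep, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    tt <- t[i0:i1] - t[i0]
    xx <- x[i0:i1] - x[i0]
    n <- seq_along(tt)
    close_frac <- cumsum(end_dist[i0:i1] <= catch_zone) / n
    dur <- tt[length(tt)]
    follow <- tt >= criteria$min_duration &
      xx > pmax(.Machine$double.eps, criteria$speed_fraction * v_z * tt) &
      close_frac >= 0.5
    # OLS slope is robust to a last-sample detachment excursion that
    # stays just inside the distance gate; distance = speed * duration
    # (the d = l*v identity of the segment observables)
    spd <- if (dur > 0) {
      unname(stats::coef(stats::lm(xx ~ tt))[2])
    } else {
      0
    }
    tibble::tibble(
      t_start = t[i0], t_end = t[i1], duration = dur,
      distance = spd * dur,
      speed = spd,
      ride_fraction = close_frac[length(close_frac)],
      persistent = any(follow))
  })
  dplyr::bind_rows(out)
}

#' Fraction of persistent end-tracking trajectories
#'
#' @param trajs A `ratchet_ensemble` (or list of trajectories).
#' @param criteria An [end_track_criteria()].
#' @return A fraction in \[0, 1\].
#' @export
propensity <- function(trajs, criteria = end_track_criteria()) {
  if (!length(trajs)) stop("empty ensemble")
  mean(vapply(trajs, function(tr) {
    classify_end_tracking(tr, criteria)$is_persistent
  }, logical(1)))
}

# Fast propensity without storing trajectories: early-stopped simulations.
screen_propensity <- function(params, n_traj, criteria, seed,
                              scenario = ratchet_scenario()) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_traj)
  hits <- 0L
  for (i in seq_len(n_traj)) {
    tr <- simulate_trajectory(params, scenario, seed = seeds[i],
                              stop_when = "persistent",
                              criteria = criteria)
    hits <- hits + attr(tr, "persistent")
  }
  hits / n_traj
}

# Per-cell time step: under the euler scheme, shrink dt where the in-well
# relaxation would make the discretization unstable (large D*U0 corner of
# phase diagrams).  The exact in-well propagator needs no adjustment.
cell_params <- function(fixed, assign) {
  for (nm in names(assign)) fixed[[nm]] <- assign[[nm]]
  fixed$D_nm <- fixed$D * 1e6
  k <- 2 * fixed$U0 / fixed$a^2
  if (identical(fixed$scheme, "euler") && k > 0) {
    theta <- k * fixed$D_nm * fixed$dt
    if (theta > 0.8) {
      fixed$dt <- 0.8 / (k * fixed$D_nm)
      fixed$record_every <- max(1L, as.integer(round(0.05 / fixed$dt)))
    }
  }
  fixed
}

#' Persistent end-tracking propensity over a two-parameter grid
#'
#' Sweeps two of `D` (um^2/s), `U0` (kBT) and `v_z` (nm/s), simulating
#' `n_traj` early-stopped trajectories per cell and recording the fraction
#' that meet the persistence criteria. The conventional phase boundary is
#' the 50% contour.
#'
#' @param axis1,axis2 Named numeric vectors of length >= 1, e.g.
#'   `list(D = c(0.001, 0.01, 0.1))`; names among `"D"`, `"U0"`, `"v_z"`.
#' @param fixed A [ratchet_params()] supplying every other parameter.
#' @param n_traj Trajectories per grid cell.
#' @param criteria An [end_track_criteria()].
#' @param seed Master seed.
#' @param threshold Phase-boundary propensity (default 0.5).
#' @return A tibble of class `ratchet_phase_diagram` with one row per
#'   cell: the two axis columns, `propensity`, `n`.
#' @export
phase_diagram <- function(axis1, axis2, fixed = ratchet_params(),
                          n_traj = 50, criteria = end_track_criteria(),
                          seed = 1L, threshold = 0.5) {
  stopifnot(length(axis1) == 1, length(axis2) == 1,
            !is.null(names(axis1)), !is.null(names(axis2)))
  n1 <- names(axis1); n2 <- names(axis2)
  stopifnot(n1 %in% c("D", "U0", "v_z"), n2 %in% c("D", "U0", "v_z"),
            n1 != n2)
  v1 <- axis1[[1]]; v2 <- axis2[[1]]
  if (!length(v1) || !length(v2)) stop("empty grid")
  grid <- tidyr::expand_grid(a1 = v1, a2 = v2)
  prop <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    assign <- stats::setNames(list(grid$a1[i], grid$a2[i]), c(n1, n2))
    p <- cell_params(fixed, assign)
    prop[i] <- screen_propensity(p, n_traj, criteria,
                                 seed = seed + 7919L * i)
  }
  out <- tibble::tibble(!!n1 := grid$a1, !!n2 := grid$a2,
                        propensity = prop, n = n_traj)
  structure(out, class = c("ratchet_phase_diagram", class(out)),
            axes = c(n1, n2), threshold = threshold)
}

#' Processivity curves: run duration and distance versus treadmilling speed
#'
#' Simulates full ensembles at each treadmilling speed, extracts the
#' end-riding runs (gap intervals in which the enzyme spends at least half
#' its samples in the catch-up zone, i.e. actually rides the end), and
#' summarises their duration and net distance with bootstrap confidence
#' intervals. The run ensemble is unconditional — short runs count — which
#' is what the closed-form theory's geometric-run averages describe; the
#' persistent (>= 4 s) counts are reported alongside. Speeds with no runs
#' are reported with `NA` summaries (missing, not zero).
#'
#' @param v_z Treadmilling speeds, nm/s.
#' @param params A [ratchet_params()]; `v_z` is overridden per speed.
#' @param n_traj Trajectories per speed.
#' @param criteria An [end_track_criteria()].
#' @param seed Master seed.
#' @param n_boot Bootstrap resamples for the CIs.
#' @param conf Confidence level.
#' @return A tibble of class `ratchet_processivity` with columns `v_z`,
#'   `n_runs`, `n_persistent`, `propensity`, `relative_propensity`,
#'   `mean_duration`, `duration_lo`, `duration_hi`, `mean_distance`,
#'   `distance_lo`, `distance_hi`.
#' @export
run_length_duration_curves <- function(v_z, params = ratchet_params(),
                                       n_traj = 100,
                                       criteria = end_track_criteria(),
                                       seed = 1L, n_boot = 1000,
                                       conf = 0.95) {
  rows <- lapply(seq_along(v_z), function(j) {
    p <- cell_params(params, list(v_z = v_z[j]))
    ens <- simulate_ensemble(p, n_traj = n_traj, seed = seed + 104729L * j,
                             criteria = criteria)
    cls <- lapply(ens, function(tr) classify_end_tracking(tr, criteria))
    runs <- dplyr::bind_rows(lapply(cls, `[[`, "runs"))
    ride <- dplyr::filter(runs, .data$ride_fraction >= 0.5)
    n_pers_traj <- sum(vapply(cls, `[[`, logical(1), "is_persistent"))
    ci <- function(v) {
      if (!length(v)) return(c(NA_real_, NA_real_, NA_real_))
      bm <- replicate(n_boot, mean(sample(v, replace = TRUE)))
      c(mean(v), stats::quantile(bm, c((1 - conf) / 2, (1 + conf) / 2),
                                 names = FALSE))
    }
    cd <- ci(ride$duration); cx <- ci(ride$distance)
    tibble::tibble(
      v_z = v_z[j], n_runs = nrow(ride),
      n_persistent = sum(ride$persistent),
      propensity = n_pers_traj / n_traj,
      mean_duration = cd[1], duration_lo = cd[2], duration_hi = cd[3],
      mean_distance = cx[1], distance_lo = cx[2], distance_hi = cx[3])
  })
  out <- dplyr::bind_rows(rows)
  total <- sum(out$propensity * n_traj)
  out <- dplyr::mutate(
    out, relative_propensity = .data$propensity * n_traj / total,
    .after = "propensity")
  structure(out, class = c("ratchet_processivity", class(out)),
            params = params, n_traj = n_traj)
}

#' Bound lifetime of an enzyme on the filament
#'
#' The bound lifetime is the first time the enzyme is more than
#' `escape_margin` beyond either filament end. For a recorded trajectory
#' this is read off the samples; [mean_bound_lifetime()] runs a dedicated
#' first-passage ensemble (mid-filament start) and reports both the naive
#' mean (censored lifetimes entered at `t_max`) and the Kaplan--Meier
#' restricted mean.
#'
#' @param traj A `ratchet_trajectory`.
#' @param escape_margin Escape distance, nm.
#' @return `bound_lifetime()`: a list with `lifetime` (s) and `censored`.
#' @export
bound_lifetime <- function(traj, escape_margin = 100) {
  et <- attr(traj, "escape_time")
  if (!is.null(et) && !is.na(et)) {
    return(list(lifetime = et, censored = FALSE))
  }
  out <- traj$x < traj$x_S - escape_margin |
    traj$x > traj$x_G + escape_margin
  if (any(out)) {
    list(lifetime = traj$t[which(out)[1]], censored = FALSE)
  } else {
    list(lifetime = traj$t[length(traj$t)], censored = TRUE)
  }
}

#' @rdname bound_lifetime
#' @param params A [ratchet_params()].
#' @param n_traj Number of first-passage trajectories.
#' @param seed Master seed.
#' @return `mean_bound_lifetime()`: a tibble with `mean_lifetime` (naive),
#'   `km_mean`, `frac_censored`, `n`, plus the per-trajectory lifetimes in
#'   attribute `lifetimes`.
#' @export
mean_bound_lifetime <- function(params = ratchet_params(), n_traj = 200,
                                seed = 1L, escape_margin = 100) {
  ens <- simulate_ensemble(params,
                           scenario = ratchet_scenario("mid_filament"),
                           n_traj = n_traj, seed = seed,
                           stop_when = "escape",
                           escape_margin = escape_margin)
  lt <- vapply(ens, function(tr) bound_lifetime(tr, escape_margin)$lifetime,
               numeric(1))
  cens <- vapply(ens, function(tr) bound_lifetime(tr, escape_margin)$censored,
                 logical(1))
  out <- tibble::tibble(
    mean_lifetime = mean(lt),
    km_mean = km_restricted_mean(lt, !cens),
    frac_censored = mean(cens), n = n_traj)
  attr(out, "lifetimes") <- tibble::tibble(lifetime = lt, censored = cens)
  out
}

# Kaplan-Meier restricted mean survival time (restriction at the largest
# observed time). With all censoring at a common t_max this coincides
# with the naive mean; kept for generality.
km_restricted_mean <- function(times, event) {
  ot <- order(times)
  times <- times[ot]; event <- event[ot]
  n <- length(times)
  at_risk <- n - seq_len(n) + 1
  surv <- cumprod(1 - event / at_risk)
  prev_t <- c(0, times[-n])
  prev_s <- c(1, surv[-n])
  sum(prev_s * (times - prev_t))
}

#' Normalized off-rate versus treadmilling speed
#'
#' The off-rate, the reciprocal of the mean bound lifetime, is the rate at
#' which enzyme molecules become free of the filament and hence available
#' for septal wall synthesis; the curve is reported relative to its value
#' at `ref_speed` (default: the slowest speed simulated).
#'
#' @param v_z Treadmilling speeds, nm/s.
#' @param params A [ratchet_params()].
#' @param n_traj First-passage trajectories per speed.
#' @param seed Master seed.
#' @param ref_speed Normalization reference (nm/s).
#' @param escape_margin Escape distance, nm.
#' @return A tibble of class `ratchet_activity` with columns `v_z`,
#'   `mean_lifetime`, `off_rate` (1/s), `relative_off_rate`,
#'   `frac_censored`, `censored_dominated` (> 50% censoring flag), `n`.
#' @export
activity_curve <- function(v_z, params = ratchet_params(), n_traj = 200,
                           seed = 1L, ref_speed = min(v_z),
                           escape_margin = 100) {
  rows <- lapply(seq_along(v_z), function(j) {
    p <- cell_params(params, list(v_z = v_z[j]))
    s <- mean_bound_lifetime(p, n_traj, seed = seed + 15485863L * j,
                             escape_margin = escape_margin)
    dplyr::mutate(s, v_z = v_z[j], .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  ref <- out$mean_lifetime[match(ref_speed, out$v_z)]
  out <- dplyr::mutate(
    out,
    off_rate = 1 / .data$mean_lifetime,
    relative_off_rate = ref / .data$mean_lifetime,
    censored_dominated = .data$frac_censored > 0.5)
  structure(out, class = c("ratchet_activity", class(out)),
            params = params, ref_speed = ref_speed)
}

#' Bracket the binding-potential depth from relative activity data
#'
#' Given measured relative synthesis-activity data as a function of
#' treadmilling speed and a measured diffusion constant, simulates the
#' model's normalized off-rate curve on a grid of well depths and returns
#' the bracket of depths whose curves are consistent with the data
#' (residual sum of squares within `rss_factor` of the best grid point).
#'
#' @param activity_data A data frame with columns `v_z` (nm/s) and
#'   `activity` (relative, 1 at the reference speed).
#' @param D Measured diffusion constant, um^2/s.
#' @param U_grid Candidate well depths, kBT.
#' @param params Base [ratchet_params()] (dt, filament geometry, t_max).
#' @param n_traj First-passage trajectories per speed and depth.
#' @param seed Master seed.
#' @param rss_factor Inclusion factor for the bracket.
#' @return A list of class `potential_fit`: `u_best`, `u_low`, `u_high`,
#'   `grid` (tibble of U0, rss), `curves` (per-depth activity curves),
#'   `data`.
#' @export
fit_binding_potential <- function(activity_data, D,
                                  U_grid = seq(4, 14, by = 1),
                                  params = ratchet_params(),
                                  n_traj = 100, seed = 1L,
                                  rss_factor = 2) {
  stopifnot(all(c("v_z", "activity") %in% names(activity_data)),
            nrow(activity_data) >= 3, D > 0)
  vz <- activity_data$v_z
  ref_speed <- vz[which.max(activity_data$activity)]
  curves <- list()
  rss <- numeric(length(U_grid))
  for (k in seq_along(U_grid)) {
    p <- params
    p$D <- D; p$D_nm <- D * 1e6; p$U0 <- U_grid[k]
    p <- cell_params(p, list())
    cur <- activity_curve(vz, p, n_traj = n_traj,
                          seed = seed + 512927L * k,
                          ref_speed = ref_speed)
    # relative activity ~ relative off-rate
    rss[k] <- sum((cur$relative_off_rate - activity_data$activity)^2)
    curves[[k]] <- cur
  }
  ok <- rss <= rss_factor * min(rss)
  if (!any(ok)) {
    stop("no candidate well depth fits the data; residuals: ",
         paste(signif(rss, 3), collapse = ", "))
  }
  structure(
    list(u_best = U_grid[which.min(rss)],
         u_low = min(U_grid[ok]), u_high = max(U_grid[ok]),
         grid = tibble::tibble(U0 = U_grid, rss = rss, in_bracket = ok),
         curves = stats::setNames(curves, U_grid),
         data = tibble::as_tibble(activity_data), D = D),
    class = "potential_fit")
}

#' @export
print.potential_fit <- function(x, ...) {
  cat("<potential_fit>\n")
  cat(sprintf("  D = %g um^2/s; best U0 = %g kBT; bracket [%g, %g] kBT\n",
              x$D, x$u_best, x$u_low, x$u_high))
  invisible(x)
}
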