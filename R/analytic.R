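#' Closed-form ratchet theory parameters
#'
#' The analytic theory describes persistent end-tracking as a sequence of
#' repeating steps, each a "stay-on" phase (escape rate \eqn{1/\tau_D}
#' competing with end-subunit loss at rate \eqn{1/\tau_Z}) followed by a
#' "catch-up" phase (mean catch-up time \eqn{\tau_C}). The end-subunit
#' lifetime is \eqn{\tau_Z = L_0 / V_Z}. The persistent regime requires
#' \eqn{\tau_D \gg \tau_Z \gg \tau_C}.
#'
#' @param tau_D Mean in-well dwell absent treadmilling, s.
#' @param tau_C Mean catch-up time, s.
#' @param tau_Z End-subunit lifetime, s; give either `tau_Z` or `v_z`.
#' @param v_z Treadmilling speed, nm/s.
#' @param L0 Subunit length, nm.
#' @return An `analytic_params` list with fields `tau_D`, `tau_C`,
#'   `tau_Z`, `v_z`, `L0`, and `persistent_regime` flag.
#' @examples
#' analytic_params(tau_D = 60, tau_C = 3e-4, v_z = 25)
#' @export
analytic_params <- function(tau_D, tau_C, tau_Z = NULL, v_z = NULL,
                            L0 = 5) {
  if (is.null(tau_Z) && is.null(v_z)) stop("give tau_Z or v_z")
  if (is.null(tau_Z)) tau_Z <- L0 / v_z
  if (is.null(v_z)) v_z <- L0 / tau_Z
  stopifnot(tau_D > 0, tau_C > 0, all(tau_Z > 0), L0 > 0)
  structure(list(tau_D = tau_D, tau_C = tau_C, tau_Z = tau_Z, v_z = v_z,
                 L0 = L0,
                 persistent_regime = all(tau_D > 10 * tau_Z) &&
                   all(tau_Z > 10 * tau_C)),
            class = "analytic_params")
}

#' Analytic step probability, step count, run length and duration
#'
#' Per repeating ratchet step the end-tracking probability is
#' \deqn{P = \exp(-(\tau_Z/\tau_D + \tau_C/\tau_Z)),}
#' the stay-on survival times the catch-up success. With geometric run
#' statistics in the continuum limit the mean number of steps is
#' \deqn{\langle N\rangle = \tau_D \tau_Z / (\tau_Z^2 + \tau_C \tau_D)}
#' (equal to \eqn{-1/\ln P}), giving mean run length
#' \eqn{\langle L\rangle = L_0 \langle N\rangle} and duration
#' \eqn{\langle T\rangle = \langle N\rangle \tau_Z}. All functions are
#' vectorised over `tau_Z`.
#'
#' @param p An [analytic_params()].
#' @return `step_probability()`: P in (0, 1]; `mean_steps()`: steps;
#'   `mean_run_length()`: nm; `mean_run_duration()`: s.
#' @examples
#' p <- analytic_params(tau_D = 60, tau_C = 3e-4, v_z = 25)
#' step_probability(p) # ~0.99518
#' mean_run_length(p)  # ~1034 nm
#' @export
step_probability <- function(p) {
  exp(-(p$tau_Z / p$tau_D + p$tau_C / p$tau_Z))
}

#' @rdname step_probability
#' @export
mean_steps <- function(p) {
  p$tau_D * p$tau_Z / (p$tau_Z^2 + p$tau_C * p$tau_D)
}

#' @rdname step_probability
#' @export
mean_run_length <- function(p) {
  p$L0 * mean_steps(p)
}

#' @rdname step_probability
#' @export
mean_run_duration <- function(p) {
  mean_steps(p) * p$tau_Z
}

#' Optimal treadmilling speed for run length
#'
#' The exponent \eqn{\tau_Z/\tau_D + \tau_C/\tau_Z} is minimized at
#' \eqn{\tau_Z^* = \sqrt{\tau_C \tau_D}}, so the mean run length peaks at
#' \deqn{V_Z^* = L_0 / \sqrt{\tau_C \tau_D}.}
#'
#' @param p An [analytic_params()].
#' @return Optimal speed, nm/s.
#' @examples
#' optimal_treadmill_speed(analytic_params(60, 3e-4, v_z = 25)) # ~37.3
#' @export
optimal_treadmill_speed <- function(p) {
  p$L0 / sqrt(p$tau_C * p$tau_D)
}

#' Analytic processivity table over a speed sweep
#'
#' @param v_z Treadmilling speeds, nm/s.
#' @param tau_D,tau_C Dwell and catch-up times, s.
#' @param L0 Subunit length, nm.
#' @return A tibble with `v_z`, `P`, `mean_steps`, `mean_run_length`,
#'   `mean_run_duration`, plus attribute `v_opt`.
#' @export
analytic_processivity <- function(v_z, tau_D, tau_C, L0 = 5) {
  p <- analytic_params(tau_D, tau_C, v_z = v_z, L0 = L0)
  out <- tibble::tibble(
    v_z = v_z,
    P = step_probability(p),
    mean_steps = mean_steps(p),
    mean_run_length = mean_run_length(p),
    mean_run_duration = mean_run_duration(p))
  structure(out, v_opt = optimal_treadmill_speed(p),
            class = c("ratchet_analytic", class(out)))
}

#' Estimate the dwell and catch-up times from targeted micro-simulations
#'
#' \eqn{\tau_D} is the mean first time an enzyme started at the center of
#' a single static binding well is found more than `d_esc` from it
#' (re-entries included), matching the distance gate used for run
#' classification. \eqn{\tau_C} is the mean first-entry time into the next
#' well for an enzyme released at the former center of a departed end
#' subunit, averaged over successful catch-ups (a catch-up fails if the
#' enzyme first drifts `fail_dist` behind).
#'
#' @param params A [ratchet_params()] (D, U0, a, L0, dt are used).
#' @param n_traj Micro-simulations per quantity.
#' @param d_esc Escape distance defining the dwell, nm.
#' @param fail_dist Catch-up failure distance, nm.
#' @param t_max_dwell,t_max_catch Censoring horizons, s.
#' @param seed Master seed.
#' @return An [analytic_params()] at the parameter set's `v_z`, with
#'   attributes `tau_D_se`, `tau_C_se`, `censored_dwell`, `catch_fail`.
#' @export
estimate_tau_d_tau_c <- function(params = ratchet_params(), n_traj = 200,
                                 d_esc = 100, fail_dist = 100,
                                 t_max_dwell = 600, t_max_catch = 10,
                                 seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s1 <- sample.int(.Machine$integer.max, n_traj)
  s2 <- sample.int(.Machine$integer.max, n_traj)
  dwell <- vapply(s1, function(s) {
    cpp_escape_time(params$D_nm, params$U0, params$a, d_esc, params$dt,
                    t_max_dwell, as.double(s), scheme_code(params))
  }, numeric(1))
  cens <- mean(is.na(dwell))
  if (cens > 0.5) {
    stop("more than half the dwell simulations were censored; ",
         "increase t_max_dwell")
  }
  catch <- vapply(s2, function(s) {
    cpp_catchup_time(params$D_nm, params$U0, params$a, params$L0,
                     fail_dist, params$dt, t_max_catch, as.double(s),
                     scheme_code(params))
  }, numeric(1))
  ok <- !is.na(catch) & catch > 0
  tau_D <- mean(dwell, na.rm = TRUE)
  tau_C <- mean(catch[ok])
  out <- analytic_params(tau_D, tau_C,
                         v_z = if (params$v_z > 0) params$v_z else NULL,
                         tau_Z = if (params$v_z > 0) NULL else Inf,
                         L0 = params$L0)
  attr(out, "tau_D_se") <- stats::sd(dwell, na.rm = TRUE) /
    sqrt(sum(!is.na(dwell)))
  attr(out, "tau_C_se") <- stats::sd(catch[ok]) / sqrt(sum(ok))
  attr(out, "censored_dwell") <- cens
  attr(out, "catch_fail") <- mean(catch < 0, na.rm = TRUE)
  out
}
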