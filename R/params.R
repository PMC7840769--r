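#' Physical and numerical parameters of the treadmilling ratchet model
#'
#' Bundles every constant of the model in fixed units: nanometres, seconds,
#' and thermal energy units (\eqn{k_BT \equiv 1}). The enzyme obeys an
#' overdamped Langevin equation \eqn{\lambda \, dx/dt = f(x) + \xi(t)} with
#' drag \eqn{\lambda = k_BT / D}; the filament treadmills rightward at
#' `v_z`, losing one subunit at the shrinking end and gaining one at the
#' growing end every `L0 / (v_z * dt)` time steps.
#'
#' @param D Enzyme free-diffusion constant, um^2/s (converted internally to
#'   nm^2/s). Typical inner-membrane proteins lie in 0.001--0.1 um^2/s.
#' @param U0 Binding-well depth in kBT (>= 0). ~10 kBT corresponds to a
#'   micromolar-range dissociation constant.
#' @param v_z Filament treadmilling speed, nm/s (>= 0).
#' @param a Half-width of the harmonic binding well, nm. Default 2.5 nm so
#'   that the wells of adjacent subunits tile the filament.
#' @param L0 Subunit length, nm (5 nm per FtsZ monomer).
#' @param n_fil Filament length in subunits (default 50, i.e. 250 nm).
#' @param dt Simulation time step, s.
#' @param t_max Maximum simulated time, s.
#' @param record_every Number of time steps between recorded samples.
#'   The default gives the 0.05 s cadence used for trajectory analysis.
#' @param scheme Integration scheme. `"exact_well"` (default) uses the
#'   exact Ornstein--Uhlenbeck propagator inside a binding well (the force
#'   is linear there, so the one-step transition density is known in
#'   closed form at any dt) and a plain Euler--Maruyama diffusive step
#'   outside; `"euler"` uses explicit Euler--Maruyama everywhere and is
#'   subject to the in-well stability/accuracy guard.
#'
#' @return An object of class `ratchet_params` (a named list). `D` is
#'   stored in nm^2/s as `D_nm`.
#' @examples
#' p <- ratchet_params(D = 0.04, U0 = 10, v_z = 25)
#' p$D_nm # 4e4 nm^2/s
#' @export
ratchet_params <- function(D = 0.04, U0 = 10, v_z = 25, a = 2.5, L0 = 5,
                           n_fil = 50, dt = 5e-6, t_max = 120,
                           record_every = round(0.05 / dt),
                           scheme = c("exact_well", "euler")) {
  scheme <- match.arg(scheme)
  stopifnot(
    "D must be > 0" = is.numeric(D) && D > 0,
    "U0 must be >= 0" = is.numeric(U0) && U0 >= 0,
    "v_z must be >= 0" = is.numeric(v_z) && v_z >= 0,
    "a must be > 0" = a > 0,
    "L0 must be > 0" = L0 > 0,
    "a must be <= L0/2" = a <= L0 / 2,
    "n_fil must be >= 2" = n_fil >= 2,
    "dt must be > 0" = dt > 0,
    "t_max must be > 0" = t_max > 0,
    "record_every must be >= 1" = record_every >= 1
  )
  if (v_z > 0 && round(L0 / (v_z * dt)) < 1) {
    stop("dt too large for this treadmilling speed: fewer than one step ",
         "per subunit lifetime")
  }
  p <- structure(
    list(D = D, D_nm = D * 1e6, U0 = U0, v_z = v_z, a = a, L0 = L0,
         n_fil = n_fil, dt = dt, t_max = t_max,
         record_every = as.integer(record_every), scheme = scheme),
    class = "ratchet_params")
  check_stability(p)
  p
}

# In-well relaxation number theta = k D dt with spring constant
# k = 2 U0 / a^2.  Explicit Euler is divergent for theta >= 2 and its
# in-well stationary variance is inflated by 2/(2 - theta), so we refuse
# clearly unstable settings and warn when the inflation exceeds ~2x.
well_relaxation_number <- function(p) {
  k <- 2 * p$U0 / p$a^2
  k * p$D_nm * p$dt
}

check_stability <- function(p) {
  theta <- well_relaxation_number(p)
  if (identical(p$scheme, "exact_well")) return(invisible(theta))
  if (theta >= 2) {
    stop(sprintf(
      paste0("unstable discretization: well relaxation number k*D*dt = ",
             "%.2f >= 2; reduce dt below %.2g s"),
      theta, 2 / (2 * p$U0 / p$a^2 * p$D_nm)))
  }
  if (theta > 1) {
    warning(sprintf(
      paste0("coarse discretization: k*D*dt = %.2f inflates the in-well ",
             "variance by %.1fx; consider a smaller dt"),
      theta, 2 / (2 - theta)), call. = FALSE)
  }
  invisible(theta)
}

#' @export
print.ratchet_params <- function(x, ...) {
  cat("<ratchet_params>\n")
  cat(sprintf("  D     = %g um^2/s (%g nm^2/s)\n", x$D, x$D_nm))
  cat(sprintf("  U0    = %g kBT,  well half-width a = %g nm\n", x$U0, x$a))
  cat(sprintf("  v_z   = %g nm/s,  filament %d x %g nm\n",
              x$v_z, x$n_fil, x$L0))
  cat(sprintf("  dt    = %g s,  t_max = %g s,  record every %d steps\n",
              x$dt, x$t_max, x$record_every))
  invisible(x)
}

#' Read / write ratchet parameters as a flat YAML config
#'
#' All quantities use (um^2/s for `D`, nm, s, kBT) as in
#' [ratchet_params()]; unknown keys are rejected.
#'
#' @param path File path.
#' @param params A `ratchet_params` object.
#' @return `read_ratchet_config()` returns a `ratchet_params`;
#'   `write_ratchet_config()` returns `path` invisibly.
#' @export
read_ratchet_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(ratchet_params))
  bad <- setdiff(names(vals), allowed)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  }
  do.call(ratchet_params, vals)
}

#' @rdname read_ratchet_config
#' @export
write_ratchet_config <- function(params, path) {
  stopifnot(inherits(params, "ratchet_params"))
  keep <- c("D", "U0", "v_z", "a", "L0", "n_fil", "dt", "t_max",
            "record_every", "scheme")
  yaml::write_yaml(params[keep], path)
  invisible(path)
}
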