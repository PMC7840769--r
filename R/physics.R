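#' Filament and enzyme state constructors
#'
#' A treadmilling filament is represented by the positions of its
#' shrinking-end (`x_S`) and growing-end (`x_G`) subunit centers, the
#' ordered subunit centers in between (spacing `L0`), and an integer
#' countdown to the next treadmilling event. The enzyme is a single 1D
#' coordinate plus the index of the subunit whose binding well it occupies
#' (if any).
#'
#' @param x_S Position of the shrinking-end subunit center, nm.
#' @param params A [ratchet_params()] object.
#' @return `filament_state()` returns a `filament_state` list;
#'   `enzyme_state()` an `enzyme_state` list.
#' @examples
#' p <- ratchet_params()
#' f <- filament_state(0, p)
#' f$x_G - f$x_S # (n_fil - 1) * L0
#' @export
filament_state <- function(x_S = 0, params = ratchet_params()) {
  centers <- x_S + (seq_len(params$n_fil) - 1) * params$L0
  period <- if (params$v_z > 0) {
    round(params$L0 / (params$v_z * params$dt))
  } else {
    Inf
  }
  structure(
    list(x_S = x_S, x_G = centers[length(centers)],
         subunit_centers = centers, steps_until_event = period,
         L0 = params$L0),
    class = "filament_state")
}

#' @rdname filament_state
#' @param x Enzyme position, nm.
#' @param filament A `filament_state`.
#' @export
enzyme_state <- function(x, filament, params = ratchet_params()) {
  stopifnot(is.finite(x))
  structure(list(x = x, bound_subunit = nearest_subunit(x, filament, params)),
            class = "enzyme_state")
}

# Index of the nearest live subunit whose well contains x, or NA.
# Ties at well boundaries resolve toward the smaller index.
nearest_subunit <- function(x, filament, params) {
  j <- floor((x - filament$x_S) / filament$L0 + 0.5)
  j <- pmin(pmax(j, 0), length(filament$subunit_centers) - 1)
  xc <- filament$x_S + j * filament$L0
  ifelse(abs(x - xc) <= params$a, j + 1, NA_integer_)
}

#' Binding potential and force of the filament landscape
#'
#' Each live subunit carries a truncated inverted-parabola well
#' \eqn{U(x) = -U_0 (1 - ((x - x_c)/a)^2)} for \eqn{|x - x_c| \le a} and 0
#' outside; the enzyme takes the well of the nearest live subunit. With the
#' default `a = L0/2` the wells tile the filament interior, the depth at
#' every subunit center is \eqn{-U_0}, entry is barrierless, and loss of
#' the end subunit leaves a flat ~5 nm stretch behind the new end.
#'
#' @param x Position(s), nm (vectorised).
#' @param filament A [filament_state()].
#' @param params A [ratchet_params()].
#' @return Energy in kBT (`binding_potential`) or force in kBT/nm
#'   (`binding_force`, \eqn{f = -dU/dx}, pulling toward the well center).
#' @examples
#' p <- ratchet_params(U0 = 10)
#' f <- filament_state(0, p)
#' binding_potential(0, f, p)   # -10 at a well minimum
#' binding_potential(2.5, f, p) # 0 at the well edge
#' @export
binding_potential <- function(x, filament, params) {
  check_filament(filament)
  vapply(x, function(xi) {
    cpp_binding_energy(xi, filament$x_S, length(filament$subunit_centers),
                       filament$L0, params$a, params$U0)
  }, numeric(1))
}

#' @rdname binding_potential
#' @export
binding_force <- function(x, filament, params) {
  check_filament(filament)
  vapply(x, function(xi) {
    cpp_binding_force(xi, filament$x_S, length(filament$subunit_centers),
                      filament$L0, params$a, params$U0)
  }, numeric(1))
}

check_filament <- function(filament) {
  if (!length(filament$subunit_centers)) {
    stop("filament is fully depolymerized: no live subunits")
  }
  invisible(filament)
}

#' Advance the enzyme by one Euler--Maruyama step
#'
#' \eqn{x \leftarrow x + D f(x) \Delta t + \sqrt{2 D \Delta t}\,\eta} with
#' \eqn{\eta \sim N(0,1)}. This is the reference R implementation of the
#' update used by the compiled trajectory driver; it is exercised by tests
#' that pin the two paths together.
#'
#' @param state An [enzyme_state()].
#' @param filament A [filament_state()].
#' @param params A [ratchet_params()].
#' @param eta Optional standard-normal draw (supply for deterministic
#'   checks; default draws from the session RNG).
#' @return A new `enzyme_state`.
#' @export
step_enzyme <- function(state, filament, params, eta = stats::rnorm(1)) {
  f <- binding_force(state$x, filament, params)
  x_new <- state$x + params$D_nm * f * params$dt +
    sqrt(2 * params$D_nm * params$dt) * eta
  if (!is.finite(x_new)) stop("non-finite enzyme position after step")
  enzyme_state(x_new, filament, params)
}

#' Advance the filament treadmilling clock by one step
#'
#' Decrements the countdown; when it reaches zero the shrinking-end
#' subunit is removed (its well vanishes), one subunit is appended at the
#' growing end, and the countdown resets to `round(L0 / (v_z dt))`.
#' Subunit count is conserved.
#'
#' @inheritParams step_enzyme
#' @param filament A [filament_state()].
#' @return A new `filament_state`.
#' @export
step_filament <- function(filament, params) {
  if (params$v_z == 0) return(filament)
  period <- round(params$L0 / (params$v_z * params$dt))
  if (period < 1) stop("dt too large for this treadmilling speed")
  filament$steps_until_event <- filament$steps_until_event - 1
  if (filament$steps_until_event == 0) {
    filament$subunit_centers <-
      c(filament$subunit_centers[-1],
        filament$subunit_centers[length(filament$subunit_centers)] +
          filament$L0)
    filament$x_S <- filament$subunit_centers[1]
    filament$x_G <- filament$subunit_centers[length(filament$subunit_centers)]
    filament$steps_until_event <- period
  }
  filament
}
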