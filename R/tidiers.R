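#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a log-normal mixture fit
#'
#' @param x A `lognormal_mixture`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`
#'   (bootstrap spread).
#' @export
tidy.lognormal_mixture <- function(x, ...) {
  terms <- c("P", "mu1", "sigma1", "mu2", "sigma2")
  tibble::tibble(
    term = terms,
    estimate = unlist(x[terms], use.names = FALSE),
    std.error = unname(x$se[terms]))
}

#' @rdname tidy.lognormal_mixture
#' @return `glance()`: a one-row tibble with `n`, `rss`, `converged`,
#'   `degenerate`.
#' @export
glance.lognormal_mixture <- function(x, ...) {
  tibble::tibble(n = x$n, rss = x$rss, converged = x$converged,
                 degenerate = x$degenerate)
}

#' Tidy an anomalous-diffusion MSD fit
#'
#' @param x An `msd_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (`D` in um^2/s, `alpha`,
#'   `D0` in nm^2) with asymptotic standard errors.
#' @export
tidy.msd_fit <- function(x, ...) {
  sm <- summary(x$nls)$coefficients
  tibble::tibble(
    term = c("D", "alpha", "D0"),
    estimate = c(x$D, x$alpha, x$D0),
    std.error = c(sm["D", "Std. Error"] * 1e-6,
                  sm["alpha", "Std. Error"],
                  sm["D0", "Std. Error"]))
}

#' @rdname tidy.msd_fit
#' @export
glance.msd_fit <- function(x, ...) {
  tibble::tibble(
    n_lags = nrow(x$fitted),
    rss = sum((x$fitted$msd - x$fitted$fit)^2),
    sigma_loc = sqrt(max(x$D0, 0) / 4))
}

#' Tidy a binding-potential bracket fit
#'
#' @param x A `potential_fit`.
#' @param ... Unused.
#' @return `tidy()`: the candidate grid with residual sums of squares;
#'   `glance()`: one row with `u_best`, `u_low`, `u_high`, `D`.
#' @export
tidy.potential_fit <- function(x, ...) {
  x$grid
}

#' @rdname tidy.potential_fit
#' @export
glance.potential_fit <- function(x, ...) {
  tibble::tibble(u_best = x$u_best, u_low = x$u_low, u_high = x$u_high,
                 D = x$D)
}
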