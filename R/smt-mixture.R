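#' Two-component log-normal mixture deconvolution of speed samples
#'
#' Directional-segment speed distributions contain a fast population that
#' rides filament treadmilling and a slow population that does not. The
#' density is
#' \deqn{f(x) = P\,\mathrm{LN}(x;\mu_1,\sigma_1) +
#'       (1-P)\,\mathrm{LN}(x;\mu_2,\sigma_2),}
#' fitted by least squares of the mixture CDF against the empirical CDF,
#' with multi-start refinement and a parametric bootstrap-by-resampling
#' spread for every parameter. Component 1 is the slower one
#' (\eqn{\mu_1 < \mu_2}); `P` is its weight.
#'
#' @param speeds Positive speed samples, nm/s (>= 30 required).
#' @param n_boot Bootstrap resamples (default 200).
#' @param n_start Number of random multi-starts.
#' @param seed Seed for starts and bootstrap.
#' @return An object of class `lognormal_mixture`: a list with `P`,
#'   `mu1`, `sigma1`, `mu2`, `sigma2`, `boot` (tibble of bootstrap
#'   estimates), `se` (named spreads), `converged`, `degenerate` (flag
#'   set when the two components coincide or one weight vanishes), and
#'   `n`.
#' @examples
#' \donttest{
#' set.seed(1)
#' sp <- c(rlnorm(300, log(8), 0.3), rlnorm(500, log(30), 0.4))
#' fit <- fit_lognormal_mixture(sp, n_boot = 20)
#' tidy(fit)
#' }
#' @export
fit_lognormal_mixture <- function(speeds, n_boot = 200, n_start = 8,
                                  seed = 1L) {
  speeds <- speeds[is.finite(speeds) & speeds > 0]
  if (length(speeds) < 30) stop("need at least 30 positive speed samples")
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  est <- fit_mixture_once(speeds, n_start)
  boot <- NULL
  if (n_boot > 0) {
    boot <- purrr::map_dfr(seq_len(n_boot), function(b) {
      bs <- sample(speeds, replace = TRUE)
      as.data.frame(fit_mixture_once(bs, max(2, n_start %/% 2))[
        c("P", "mu1", "sigma1", "mu2", "sigma2")])
    })
    boot <- tibble::as_tibble(boot)
  }
  se <- if (!is.null(boot)) {
    vapply(boot, stats::sd, numeric(1))
  } else {
    stats::setNames(rep(NA_real_, 5),
                    c("P", "mu1", "sigma1", "mu2", "sigma2"))
  }
  degenerate <- est$P < 0.02 || est$P > 0.98 ||
    (abs(est$mu1 - est$mu2) < 0.05 && abs(est$sigma1 - est$sigma2) < 0.05)
  structure(c(est, list(boot = boot, se = se, degenerate = degenerate,
                        n = length(speeds))),
            class = "lognormal_mixture")
}

mixture_cdf <- function(x, P, mu1, s1, mu2, s2) {
  P * stats::plnorm(x, mu1, s1) + (1 - P) * stats::plnorm(x, mu2, s2)
}

fit_mixture_once <- function(x, n_start) {
  xs <- sort(x)
  n <- length(xs)
  ecdf_y <- (seq_len(n) - 0.5) / n
  lx <- log(xs)
  obj <- function(par) {
    P <- stats::plogis(par[1])
    m1 <- par[2]; s1 <- exp(par[3]); m2 <- par[4]; s2 <- exp(par[5])
    sum((mixture_cdf(xs, P, m1, s1, m2, s2) - ecdf_y)^2)
  }
  q <- stats::quantile(lx, c(0.25, 0.75))
  starts <- list(c(0, q[1], log(stats::sd(lx) / 2 + 1e-3),
                   q[2], log(stats::sd(lx) / 2 + 1e-3)))
  for (i in seq_len(n_start - 1)) {
    starts[[i + 1]] <- c(stats::rnorm(1, 0, 1),
                         stats::rnorm(1, q[1], 0.5),
                         stats::rnorm(1, -1, 0.5),
                         stats::rnorm(1, q[2], 0.5),
                         stats::rnorm(1, -1, 0.5))
  }
  best <- NULL; best_val <- Inf; conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(stats::optim(s, obj, method = "Nelder-Mead",
                                 control = list(maxit = 2000)),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$value < best_val) {
      best <- fit$par; best_val <- fit$value
      conv <- fit$convergence == 0
    }
  }
  if (is.null(best)) stop("mixture fit failed to converge from any start")
  best <- unname(best)
  P <- stats::plogis(best[1])
  m1 <- best[2]; s1 <- exp(best[3]); m2 <- best[4]; s2 <- exp(best[5])
  if (m1 > m2) { # enforce component ordering mu1 < mu2
    tmp <- c(m1, s1); m1 <- m2; s1 <- s2; m2 <- tmp[1]; s2 <- tmp[2]
    P <- 1 - P
  }
  list(P = P, mu1 = m1, sigma1 = s1, mu2 = m2, sigma2 = s2,
       rss = best_val, converged = conv)
}

#' @export
print.lognormal_mixture <- function(x, ...) {
  cat("<lognormal_mixture>\n")
  cat(sprintf("  slow: P = %.3f, meanlog %.3f, sdlog %.3f (exp(mu) = %.1f)\n",
              x$P, x$mu1, x$sigma1, exp(x$mu1)))
  cat(sprintf("  fast: P = %.3f, meanlog %.3f, sdlog %.3f (exp(mu) = %.1f)\n",
              1 - x$P, x$mu2, x$sigma2, exp(x$mu2)))
  if (x$degenerate) cat("  note: degenerate/weakly identified components\n")
  invisible(x)
}

#' Resample away the slow population of a speed distribution
#'
#' Using a fitted mixture, removes from each histogram bin a random subset
#' of samples matching the slow component's expected count in that bin,
#' repeated `n_rounds` times. The returned subsets approximate draws from
#' the fast component alone (removing with a per-sample probability
#' instead would scale both components equally and not deconvolve).
#'
#' @param speeds Speed samples, nm/s.
#' @param fit A [fit_lognormal_mixture()] result (component 1 = slow).
#' @param n_rounds Number of resampling rounds (default 100).
#' @param breaks Histogram bin specification passed to [hist()]
#'   (default Freedman--Diaconis).
#' @param seed Seed.
#' @return A list of `n_rounds` numeric vectors (fast-population
#'   subsets), with attribute `expected_kept` (expected fast fraction).
#' @export
resample_fast_population <- function(speeds, fit, n_rounds = 100,
                                     breaks = "FD", seed = 1L) {
  stopifnot(inherits(fit, "lognormal_mixture"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  h <- graphics::hist(speeds, breaks = breaks, plot = FALSE)
  bin <- findInterval(speeds, h$breaks, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1), length(h$mids))
  n <- length(speeds)
  # expected slow-component count per bin from the fitted CDF
  slow_mass <- diff(stats::plnorm(h$breaks, fit$mu1, fit$sigma1))
  n_slow <- fit$P * n * slow_mass
  if (fit$P >= 0.98) {
    warning("slow fraction ~1: resampled output is near-empty")
  }
  out <- lapply(seq_len(n_rounds), function(r) {
    drop_idx <- unlist(lapply(seq_along(h$mids), function(bb) {
      members <- which(bin == bb)
      k <- min(length(members), round(n_slow[bb]))
      if (k > 0) sample(members, k) else integer(0)
    }))
    if (length(drop_idx)) as.numeric(speeds[-drop_idx]) else
      as.numeric(speeds)
  })
  attr(out, "expected_kept") <- 1 - fit$P
  out
}
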