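#' Expected number of bridge nodes created at one insertion step
#'
#' Conditional on the new node arriving at radial distance `r`, the number of
#' its `m` nearest targets lying outside the effective reach `T_eff` is a
#' function of how many of the `j` existing nodes fall inside the reach. With
#' `p` the coverage fraction of the `T_eff`-disk (see [coverage_fraction()]),
#' the count of inside nodes is Binomial(`j`, `p`), and the expectation is
#'
#'   `beta_j(r) = sum_{i=0}^{min(m-1, j-1)} min(m-i, j-i) C(j,i) p^i (1-p)^(j-i)`.
#'
#' Binomial coefficients are evaluated through `lgamma` so that `j` of a few
#' thousand (and the non-integer effective node counts produced by the
#' recursion) pose no overflow problem.
#'
#' @param j number of existing nodes (may be non-integer when fed from the
#'   recursion's effective node count).
#' @param r radial position(s) of the arriving node; vectorized.
#' @param T_eff effective reach radius (threshold times the square root of
#'   the mean degree).
#' @param R disk radius.
#' @param m attachment count.
#' @return expected bridge-node counts in `[0, min(m, j)]`, one per `r`.
#' @export
step_bridge_expectation <- function(j, r, T_eff, R, m) {
  if (j < 1) stop("'j' must be at least 1")
  p <- coverage_fraction(r, T_eff, R)
  imax <- min(m - 1, floor(j - 1 + 1e-9))
  if (imax < 0) return(numeric(length(r)))
  out <- numeric(length(r))
  logp <- ifelse(p > 0, log(p), -Inf)
  log1mp <- ifelse(p < 1, log1p(-p), -Inf)
  for (i in 0:imax) {
    lc <- lgamma(j + 1) - lgamma(i + 1) - lgamma(j - i + 1)
    lt <- lc + i * logp + (j - i) * log1mp
    # p = 0 with i = 0 (or p = 1 with i = j) give 0 * -Inf; fix up directly
    lt[p == 0] <- if (i == 0) lc else -Inf
    lt[p == 1] <- if (abs(j - i) < 1e-12) lc else -Inf
    out <- out + min(m - i, j - i) * exp(lt)
  }
  out
}

#' Expected mean degree after l random-node insertions
#'
#' Counting argument: with `l` random nodes placed the direct attachments
#' contribute `l m - m (m + 1) / 2` edges when
#' `l > m` (or `l (l - 1) / 2` while the network is smaller than the
#' attachment count), and each expected bridge contributes two edges in this
#' bookkeeping; the node count is `l` plus the accumulated expected bridges.
#'
#' @param l number of random nodes placed (`>= 1`; non-integer values are
#'   accepted for use inside the recursion).
#' @param m attachment count.
#' @param cumB accumulated expected number of bridge nodes up to step `l`.
#' @return the expected mean degree; 0 at `l = 1` with no bridges.
#' @export
mean_degree_estimate <- function(l, m, cumB = 0) {
  if (any(l < 1)) stop("'l' must be at least 1")
  num <- ifelse(l > m,
                l * m - m * (m + 1) / 2 + 2 * cumB,
                l * (l - 1) / 2 + 2 * cumB)
  2 * num / (l + cumB)
}

#' Recursion for the expected number of bridge nodes
#'
#' Iterates the analytic estimate of the bridge-node production of the
#' growing model: at each step the expected count of new bridges is the
#' radial average (density `2 r / R^2` on the disk) of
#' [step_bridge_expectation()], evaluated with the effective reach
#' `T * sqrt(kbar)` where `kbar` is the running mean-degree estimate of
#' [mean_degree_estimate()]. The radial integral is computed with fixed-order
#' Gauss--Legendre quadrature, so the output is deterministic and
#' bit-reproducible.
#'
#' By default `kbar` is floored at 1 inside the effective reach, mirroring
#' the generator's degree floor; `strict = TRUE` uses the raw `kbar` (which
#' starts at 0 and therefore predicts spurious bridges in the first steps for
#' any threshold).
#'
#' @param N number of random-node insertion steps.
#' @param m attachment count.
#' @param R disk radius.
#' @param T effective-distance threshold.
#' @param quad_nodes Gauss--Legendre order for the radial integral.
#' @param strict if `TRUE`, do not floor the mean degree at 1.
#' @return an object of class `bridge_recursion` with elements
#'   \describe{
#'     \item{b}{expected new bridges per step (`b[1] = 0`).}
#'     \item{B}{cumulative expected bridges, `cumsum(b)`.}
#'     \item{kbar}{mean-degree estimates per step.}
#'     \item{j}{effective node counts `l + B[l]`.}
#'     \item{params}{the input parameters.}
#'   }
#' @examples
#' rec <- bridge_recursion(N = 200, m = 3, R = 50, T = 12)
#' rec
#' @export
bridge_recursion <- function(N, m = 3, R = 50, T, quad_nodes = 256,
                             strict = FALSE) {
  if (!is.numeric(N) || N < 1 || N != round(N))
    stop("'N' must be a positive integer")
  if (R <= 0 || T <= 0 || m < 1) stop("invalid parameters")
  gl <- pracma::gaussLegendre(quad_nodes, 0, R)
  wdens <- gl$w * 2 * gl$x / R^2

  b <- numeric(N)
  kbar <- numeric(N)
  b[1] <- 0
  kbar[1] <- 0
  cumB <- 0
  for (l in seq_len(N - 1L)) {
    kb <- mean_degree_estimate(l, m, cumB)
    kbar[l] <- kb
    keff <- if (strict) kb else max(kb, 1)
    T_eff <- T * sqrt(keff)
    j <- l + cumB
    beta <- step_bridge_expectation(j, gl$x, T_eff, R, m)
    bl <- sum(wdens * beta)
    if (!is.finite(bl))
      stop(sprintf("recursion produced a non-finite value at step %d", l + 1L))
    b[l + 1L] <- bl
    cumB <- cumB + bl
  }
  if (N > 1) kbar[N] <- mean_degree_estimate(N, m, cumB)
  structure(list(b = b, B = cumsum(b), kbar = kbar,
                 j = seq_len(N) + cumsum(b),
                 params = list(N = N, m = m, R = R, T = T,
                               quad_nodes = quad_nodes, strict = strict)),
            class = "bridge_recursion")
}

#' @export
print.bridge_recursion <- function(x, ...) {
  p <- x$params
  N <- p$N
  cat(sprintf("Bridge-node recursion: N = %d, m = %d, R = %g, T = %g\n",
              N, p$m, p$R, p$T))
  cat(sprintf("  expected total bridges B_N = %.4f (last step b_N = %.3e)\n",
              x$B[N], x$b[N]))
  invisible(x)
}

#' @export
plot.bridge_recursion <- function(x, which = c("B", "b"), ...) {
  which <- match.arg(which)
  l <- seq_along(x$b)
  if (which == "B")
    plot(l, x$B, type = "l", xlab = "step", ylab = "cumulative bridges B",
         ...)
  else
    plot(l, x$b, type = "l", log = "y", xlab = "step",
         ylab = "expected new bridges b", ...)
  invisible(x)
}

#' Fit the asymptotic decay of the per-step bridge expectation
#'
#' The per-step bridge expectation decays approximately as
#' `b_N = exp(-f1 N + f2 log N + f3)`; taking logs makes this linear in
#' `(-N, log N, 1)` and the three coefficients are obtained by ordinary
#' least squares on the chosen window.
#'
#' @param b positive sequence of per-step expectations (e.g. the `b` element
#'   of a [bridge_recursion()] result), indexed by step number.
#' @param window integer indices of the points to fit; the default keeps the
#'   entries above `1e-8 * max(b)`. (An unrestricted window lets the
#'   numerically negligible far tail dominate the log-space least squares
#'   and distorts the implied limit.)
#' @return an object of class `asymptotic_fit` with the named coefficients
#'   `f1` (decay rate), `f2` (log coefficient) and `f3` (offset), plus the
#'   fit window and residuals. `coef()`, `predict()` (expected `b_N` at new
#'   step numbers) and `print()` methods are available.
#' @seealso [bridge_limit()] for the implied total bridge count.
#' @examples
#' b <- exp(-0.05 * (1:200) + 1.5 * log(1:200) - 2)
#' coef(fit_asymptotic_decay(b))
#' @export
fit_asymptotic_decay <- function(b, window = NULL) {
  if (is.null(window)) window <- which(b > 1e-8 * max(b, na.rm = TRUE))
  window <- as.integer(window)
  if (length(window) < 3) stop("need at least 3 points to fit the decay")
  bw <- b[window]
  if (any(!is.finite(bw)) || any(bw <= 0))
    stop("all values in the fit window must be positive and finite")
  y <- log(bw)
  X <- cbind(`-N` = -window, logN = log(window), offset = 1)
  cf <- stats::lm.fit(X, y)$coefficients
  f <- c(f1 = unname(cf[1]), f2 = unname(cf[2]), f3 = unname(cf[3]))
  fitted <- drop(X %*% cf)
  structure(list(coefficients = f, window = window,
                 fitted = exp(fitted), residuals = y - fitted),
            class = "asymptotic_fit")
}

#' @export
print.asymptotic_fit <- function(x, ...) {
  f <- x$coefficients
  cat(sprintf("Asymptotic decay fit: b_N ~ exp(-%.5g N %+.5g log N %+.5g)\n",
              f[["f1"]], f[["f2"]], f[["f3"]]))
  cat(sprintf("  window: steps %d..%d (%d points)\n",
              min(x$window), max(x$window), length(x$window)))
  if (f[["f1"]] > 0)
    cat(sprintf("  implied limit of total bridges: %.4f\n", bridge_limit(x)))
  invisible(x)
}

#' @export
predict.asymptotic_fit <- function(object, newdata = object$window, ...) {
  f <- object$coefficients
  N <- as.numeric(newdata)
  exp(-f[["f1"]] * N + f[["f2"]] * log(N) + f[["f3"]])
}

#' Generalized exponential integral
#'
#' Computes `E_nu(x) = integral_1^Inf exp(-x t) t^(-nu) dt` for real order
#' `nu` and `x > 0`, via the upper incomplete gamma function
#' `E_nu(x) = x^(nu - 1) Gamma(1 - nu, x)`; negative-parameter incomplete
#' gamma values are obtained by upward recurrence from `Gamma(0, x) = E_1(x)`
#' or the regularized gamma on the positive side.
#'
#' @param nu real order.
#' @param x positive argument.
#' @return the value of `E_nu(x)`.
#' @examples
#' expint_en(0, 1)  # exp(-1): E_0(x) = exp(-x)/x
#' @export
expint_en <- function(nu, x) {
  if (x <= 0) stop("'x' must be positive")
  x^(nu - 1) * .gamma_inc_upper(1 - nu, x)
}

# upper incomplete gamma Gamma(a, x) for any real a, x > 0
.gamma_inc_upper <- function(a, x) {
  if (a > 1e-10)
    return(exp(lgamma(a) +
                 stats::pgamma(x, a, lower.tail = FALSE, log.p = TRUE)))
  if (abs(a) <= 1e-10)
    return(pracma::expint_E1(x))
  (.gamma_inc_upper(a + 1, x) - x^a * exp(-x)) / a
}

#' Limiting total number of bridge nodes
#'
#' Integrating the fitted decay `exp(-f1 x + f2 log x + f3)` from 1 to
#' infinity gives the closed form `exp(f3) * E_{-f2}(f1)` for the limiting
#' total bridge count, with `E` the generalized exponential integral
#' ([expint_en()]). Requires a positive decay rate `f1`.
#'
#' @param fit an `asymptotic_fit`, or a numeric vector of the three
#'   coefficients `(f1, f2, f3)`.
#' @return the limiting total bridge count.
#' @export
bridge_limit <- function(fit) {
  f <- if (inherits(fit, "asymptotic_fit")) fit$coefficients else fit
  if (length(f) != 3) stop("need the three coefficients f1, f2, f3")
  f1 <- f[[1]]; f2 <- f[[2]]; f3 <- f[[3]]
  if (!is.finite(f1) || f1 <= 0)
    stop("the decay rate f1 must be positive for the integral to converge")
  exp(f3) * expint_en(-f2, f1)
}
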