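## Finite-size relation between system size t and vocabulary N.
##
## Under a Zipf law z(r) = A r^(-alpha) whose least frequent element occurs
## once (A = N^alpha), replacing the rank sum by an integral gives the
## closed form
##     t(N) = (N - N^alpha) / (1 - alpha),       alpha != 1,
## with the limit t = N log N at alpha = 1, inverted there by the principal
## Lambert-W branch, N = t / W0(t).

## numerically stable form of (N - N^alpha)/(1 - alpha); continuous at
## alpha -> 1 where it tends to N log N
.tsize <- function(N, alpha) {
  lN <- log(N)
  d <- (alpha - 1) * lN
  ifelse(abs(d) < 1e-8, N * lN * (1 + d / 2), N * (-expm1(d)) / (1 - alpha))
}

#' System size implied by a vocabulary size
#'
#' Evaluates the continuous-approximation relation
#' \eqn{t(N) = (N - N^{\alpha})/(1 - \alpha)}: the total number of
#' occurrences in a system that obeys Zipf's law with exponent `alpha` and
#' contains `N` distinct elements. The map is strictly increasing in `N`
#' with \eqn{t(1) = 0}, and tends to \eqn{N \log N} as
#' \eqn{\alpha \to 1}.
#'
#' @param N Vocabulary size, numeric vector with all values >= 1. Treated
#'   as continuous; no rounding is applied.
#' @param alpha Zipf exponent, a single positive value. Exactly 1 is
#'   rejected; use [vocab_from_text_size()], which routes the unit exponent
#'   to the Lambert-W branch (values arbitrarily close to 1 are fine: the
#'   implementation is continuous through the limit).
#' @return The system size `t(N)`, same length as `N`.
#' @examples
#' text_size_from_vocab(4, 0.5)  # 4
#' text_size_from_vocab(3, 2)    # 6
#' @export
text_size_from_vocab <- function(N, alpha) {
  stopifnot(is.numeric(N), is.numeric(alpha), length(alpha) == 1)
  if (!is.finite(alpha) || alpha <= 0) {
    stop("`alpha` must be positive and finite", call. = FALSE)
  }
  if (alpha == 1) {
    stop("alpha = 1 has no closed form here; use the Lambert-W branch via vocab_from_text_size()",
         call. = FALSE)
  }
  if (any(!is.finite(N)) || any(N < 1)) {
    stop("`N` must be finite and >= 1", call. = FALSE)
  }
  .tsize(N, alpha)
}

## largest N with t(N) <= size, by expanding bracket + uniroot
.vocab_root <- function(size, alpha) {
  f <- function(N) .tsize(N, alpha) - size
  if (f(1) >= 0) return(1)
  hi <- 2
  while (f(hi) < 0) hi <- hi * 2
  r <- uniroot(f, c(1, hi), tol = .Machine$double.eps^0.75)$root
  ## polish with one Newton step on log N for tight |t(N)-t|/t
  for (i in 1:2) {
    tt <- .tsize(r, alpha)
    dt <- (1 - alpha * r^(alpha - 1)) / (1 - alpha)  # dt/dN
    step <- (size - tt) / dt
    if (is.finite(step) && abs(step) < 0.5 * r) r <- r + step
  }
  r
}

#' Vocabulary size implied by a system size
#'
#' Inverts the finite-size relation: returns the number of distinct
#' elements `N` such that [text_size_from_vocab()] equals `t`, by bracketed
#' root finding on the strictly monotone forward map. For
#' \eqn{|\alpha - 1| < 10^{-6}} the closed-form Lambert-W branch
#' \eqn{N = t / W_0(t)} is used, which satisfies \eqn{N \log N = t}
#' exactly.
#'
#' @param t System size (total occurrences), positive numeric vector.
#' @param alpha Zipf exponent, single positive value.
#' @return Vocabulary size `N >= 1`, same length as `t`.
#' @examples
#' vocab_from_text_size(4, 0.5)           # 4
#' vocab_from_text_size(exp(1), 1)        # e (since W0(e) = 1)
#' vocab_from_text_size(10 * log(10), 1)  # 10
#' @export
vocab_from_text_size <- function(t, alpha) {
  stopifnot(is.numeric(t), is.numeric(alpha), length(alpha) == 1)
  if (!is.finite(alpha) || alpha <= 0) {
    stop("`alpha` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("`t` must be positive and finite", call. = FALSE)
  }
  if (abs(alpha - 1) < 1e-6) {
    return(ifelse(t < 1e-12, 1, t / pracma::lambertWp(t)))
  }
  vapply(t, .vocab_root, numeric(1), alpha = alpha)
}

## ---- improved (discrete-normalization) variant ----------------------------

## Hurwitz zeta via Euler-Maclaurin; s != 1, a >= 1
.hzeta <- function(s, a, K = 25L) {
  k <- 0:(K - 1)
  aK <- a + K
  sum((a + k)^(-s)) + aK^(1 - s) / (s - 1) + 0.5 * aK^(-s) +
    s * aK^(-s - 1) / 12 -
    s * (s + 1) * (s + 2) * aK^(-s - 3) / 720 +
    s * (s + 1) * (s + 2) * (s + 3) * (s + 4) * aK^(-s - 5) / 30240
}

## generalized partial sum sum_{r=1}^{N} r^(-alpha), continuous in N
.zipf_psum <- function(N, alpha) {
  if (abs(alpha - 1) < 1e-12) return(digamma(N + 1) - digamma(1))
  .hzeta(alpha, 1) - .hzeta(alpha, N + 1)
}

## Zipf prefactor A from the discrete normalization N * zeta(beta, A) = zeta(beta)
.zipf_prefactor <- function(N, beta) {
  if (N <= 1) return(1)
  zb <- .hzeta(beta, 1)
  f <- function(A) N * .hzeta(beta, A) - zb
  hi <- 2
  while (f(hi) > 0) hi <- hi * 2
  uniroot(f, c(1, hi), tol = 1e-10)$root
}

## improved forward map t(N)
.tsize_improved <- function(N, alpha) {
  if (N <= 1) return(N)
  .zipf_prefactor(N, 1 + 1 / alpha) * .zipf_psum(N, alpha)
}

#' Vocabulary size from the improved (discrete-normalization) relation
#'
#' A refinement of [vocab_from_text_size()] that avoids the two continuous
#' approximations of the basic relation. The Zipf prefactor `A` is taken
#' from the discrete normalization of the frequency density,
#' \eqn{N\,\zeta(\beta, A) = \zeta(\beta)} with \eqn{\beta = 1 + 1/\alpha}
#' (Hurwitz zeta), instead of the continuum estimate \eqn{A = N^{\alpha}};
#' the system size is then the exact rank sum
#' \eqn{t = A \sum_{r \le N} r^{-\alpha}}. The resulting curve has almost
#' the same log-log slope as the basic relation but a different level,
#' and tracks empirical vocabularies more closely.
#'
#' @param t System size, numeric vector with values >= 1.
#' @param alpha Zipf exponent, single positive value.
#' @return Vocabulary size `N >= 1`, same length as `t`.
#' @examples
#' vocab_from_text_size_improved(1, 0.7)  # 1
#' @export
vocab_from_text_size_improved <- function(t, alpha) {
  stopifnot(is.numeric(t), is.numeric(alpha), length(alpha) == 1)
  if (!is.finite(alpha) || alpha <= 0) {
    stop("`alpha` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t < 1)) {
    stop("`t` must be finite and >= 1", call. = FALSE)
  }
  one <- function(tt) {
    if (tt <= 1) return(1)
    f <- function(N) .tsize_improved(N, alpha) - tt
    hi <- 2
    while (f(hi) < 0) hi <- hi * 2
    uniroot(f, c(1, hi), tol = 1e-9)$root
  }
  vapply(t, one, numeric(1))
}

## ---- model curve and finite-size Heaps exponent ---------------------------

## Vocabulary grid for fitting: the relation evaluated at (effectively) every
## integer vocabulary size 2..N(size); above `grid_size` points the grid is
## subsampled linearly in N, which preserves the least-squares weighting.
.relation_grid <- function(alpha, size, grid_size, variant = "basic") {
  tmax_fun <- switch(variant,
                     basic = function(s) {
                       if (abs(alpha - 1) < 1e-6) s / pracma::lambertWp(s) else .vocab_root(s, alpha)
                     },
                     improved = function(s) vocab_from_text_size_improved(s, alpha))
  M <- tmax_fun(size)
  if (M < 3) stop("degenerate grid: fewer than 2 usable vocabulary points", call. = FALSE)
  Ng <- if (M - 1 <= grid_size) seq(2, floor(M)) else seq(2, M, length.out = grid_size)
  tfun <- switch(variant,
                 basic = function(N) .tsize(N, if (abs(alpha - 1) < 1e-6) 1 else alpha),
                 improved = function(N) vapply(N, .tsize_improved, numeric(1), alpha = alpha))
  list(t = tfun(Ng), N = Ng)
}

#' Finite-size Heaps exponent from the analytical relation
#'
#' Builds the model curve `N(t)` implied by the finite-size relation for a
#' Zipf exponent `alpha` and total system size `size`, and returns the
#' ordinary least-squares slope of `log N` against `log t`. The curve is
#' evaluated at every integer vocabulary size up to the final vocabulary
#' `N(size)` (subsampled linearly beyond `grid_size` points). Unlike the
#' asymptotic exponent of [asymptotic_heaps()], this value depends on the
#' system size and lies below it, most visibly for `alpha` near 1.
#'
#' @param alpha Zipf exponent, single positive value (the unit exponent is
#'   handled by the Lambert-W branch).
#' @param size Total system size `T`, >= 10.
#' @param grid_size Maximum number of grid points (>= 50); the default
#'   keeps the fit within 1e-3 of the full integer grid.
#' @param details If `TRUE`, return a list with the slope, intercept and
#'   R-squared of the log-log fit instead of the bare slope.
#' @return The finite-size Heaps exponent in (0, 1], or a list when
#'   `details = TRUE`.
#' @examples
#' heaps_exponent_numeric(1.323, 206779)  # ~0.725
#' @export
heaps_exponent_numeric <- function(alpha, size, grid_size = 1e5, details = FALSE) {
  stopifnot(is.numeric(alpha), length(alpha) == 1,
            is.numeric(size), length(size) == 1)
  if (!is.finite(alpha) || alpha <= 0) {
    stop("`alpha` must be positive and finite", call. = FALSE)
  }
  if (!is.finite(size) || size < 10) stop("`size` must be >= 10", call. = FALSE)
  if (grid_size < 50) stop("`grid_size` must be >= 50", call. = FALSE)
  g <- .relation_grid(alpha, size, grid_size)
  lx <- log(g$t)
  ly <- log(g$N)
  slope <- stats::cov(lx, ly) / var(lx)
  if (!details) return(slope)
  list(lambda = slope,
       intercept = mean(ly) - slope * mean(lx),
       r_squared = stats::cor(lx, ly)^2,
       n_points = length(lx))
}

#' Model-implied growth curve N(t)
#'
#' Tabulates the finite-size relation on a geometric grid of system sizes,
#' for plotting or export. `variant = "improved"` uses the
#' discrete-normalization relation of [vocab_from_text_size_improved()].
#'
#' @inheritParams heaps_exponent_numeric
#' @param grid_size Number of grid points along `t`.
#' @param variant `"basic"` or `"improved"`.
#' @return An object of class `"relation_curve"`: a data frame with columns
#'   `t` and `N`, with attributes `alpha`, `size` and `variant`.
#' @export
relation_curve <- function(alpha, size, grid_size = 1000, variant = c("basic", "improved")) {
  variant <- match.arg(variant)
  stopifnot(is.finite(alpha), alpha > 0, is.finite(size), size >= 10)
  tg <- exp(seq(0, log(size), length.out = grid_size))
  N <- if (variant == "basic") {
    vocab_from_text_size(tg, alpha)
  } else {
    vocab_from_text_size_improved(pmax(tg, 1), alpha)
  }
  structure(data.frame(t = tg, N = N),
            alpha = alpha, size = size, variant = variant,
            class = c("relation_curve", "data.frame"))
}

#' Error of the rank-sum to integral approximation
#'
#' The basic finite-size relation replaces \eqn{\sum_{r=1}^{N} r^{-\alpha}}
#' by \eqn{\int_1^N r^{-\alpha}\,dr}. The sum always exceeds the integral;
#' the relative error grows with `alpha` and shrinks with `N`.
#'
#' @param alpha Zipf exponent, positive.
#' @param N Number of ranks summed, integer >= 2.
#' @return A list of class `"approximation_error"` with elements
#'   `alpha`, `N`, `sum_value`, `integral_value` and
#'   `rel_error = (sum - integral)/sum`.
#' @examples
#' sum_integral_error(2, 2)  # sum 1.25, integral 0.5, rel_error 0.6
#' @export
sum_integral_error <- function(alpha, N) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, is.numeric(N), length(N) == 1)
  if (!is.finite(alpha) || alpha <= 0) {
    stop("`alpha` must be positive and finite", call. = FALSE)
  }
  if (!is.finite(N) || N < 2 || N != floor(N)) {
    stop("`N` must be an integer >= 2", call. = FALSE)
  }
  s <- if (N <= 2e6) sum(seq_len(N)^(-alpha)) else .zipf_psum(N, alpha)
  i <- if (abs(alpha - 1) < 1e-12) log(N) else (N^(1 - alpha) - 1) / (1 - alpha)
  structure(list(alpha = alpha, N = N, sum_value = s, integral_value = i,
                 rel_error = (s - i) / s),
            class = "approximation_error")
}

#' @export
print.approximation_error <- function(x, ...) {
  cat(sprintf("sum = %.6g, integral = %.6g, relative error = %.4g (alpha = %g, N = %d)\n",
              x$sum_value, x$integral_value, x$rel_error, x$alpha, x$N))
  invisible(x)
}
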