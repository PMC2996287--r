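#' Convert a Zipf (rank) exponent to a frequency-density exponent
#'
#' For a system whose rank-frequency table obeys \eqn{z(r) \propto r^{-\alpha}},
#' the probability density of the frequency itself obeys
#' \eqn{p(z) \propto z^{-\beta}} with \eqn{\beta = 1 + 1/\alpha}.
#'
#' @param alpha Zipf (rank) exponent, a positive numeric vector.
#' @return The density exponent \eqn{\beta = 1 + 1/\alpha}.
#' @seealso [alpha_from_beta()] for the inverse mapping.
#' @examples
#' beta_from_alpha(1)    # 2
#' beta_from_alpha(0.5)  # 3
#' @export
beta_from_alpha <- function(alpha) {
  stopifnot(is.numeric(alpha))
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("`alpha` must be positive and finite", call. = FALSE)
  }
  1 + 1 / alpha
}

#' Convert a frequency-density exponent to a Zipf (rank) exponent
#'
#' Inverse of [beta_from_alpha()]: \eqn{\alpha = 1/(\beta - 1)}. A density
#' exponent at or below 1 has no corresponding rank exponent.
#'
#' @param beta Density exponent of \eqn{p(z) \propto z^{-\beta}}; must
#'   exceed 1.
#' @return The rank exponent \eqn{\alpha}.
#' @examples
#' alpha_from_beta(2.1)  # degree-distribution exponent 2.1 -> alpha ~ 0.909
#' @export
alpha_from_beta <- function(beta) {
  stopifnot(is.numeric(beta))
  if (any(!is.finite(beta)) || any(beta <= 1)) {
    stop("`beta` must be finite and > 1", call. = FALSE)
  }
  1 / (beta - 1)
}

#' Asymptotic Heaps exponent implied by a Zipf exponent
#'
#' In the infinite-size limit the number of distinct elements grows as
#' \eqn{N(t) \propto t^{\lambda}} with \eqn{\lambda = 1} for
#' \eqn{\alpha \le 1} and \eqn{\lambda = 1/\alpha} for \eqn{\alpha > 1}.
#' The function is continuous at \eqn{\alpha = 1}. Finite systems fall
#' short of this value; see [heaps_exponent_numeric()].
#'
#' @param alpha Zipf exponent, positive numeric vector.
#' @return Asymptotic Heaps exponent in (0, 1].
#' @examples
#' asymptotic_heaps(c(0.5, 1, 2))  # 1 1 0.5
#' @export
asymptotic_heaps <- function(alpha) {
  stopifnot(is.numeric(alpha))
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("`alpha` must be positive and finite", call. = FALSE)
  }
  ifelse(alpha <= 1, 1, 1 / alpha)
}

#' Accelerating exponent for a growing scale-free system
#'
#' Maps the finite-size Heaps exponent to the accelerating exponent
#' \eqn{\theta = 1/\lambda}: in a growing network whose degree sequence is
#' Zipf-distributed with rank exponent `alpha`, the total degree scales with
#' the number of nodes as \eqn{t \propto N^{\theta}}. For `alpha > 1`,
#' \eqn{\theta \to \alpha} as the system size grows.
#'
#' @inheritParams heaps_exponent_numeric
#' @return Accelerating exponent \eqn{\theta \ge 1}.
#' @export
accelerating_exponent <- function(alpha, size, grid_size = 1e5) {
  1 / heaps_exponent_numeric(alpha, size, grid_size)
}

#' Construct a rank-frequency table
#'
#' The Zipf's-law object: frequencies of distinct elements sorted in
#' non-increasing order and indexed by rank. `M` is the number of distinct
#' elements and `T` the total number of occurrences.
#'
#' @param freqs Positive frequencies (any order; sorted internally).
#' @param labels Optional element identifiers aligned with `freqs`; used to
#'   break frequency ties deterministically (lexicographic order).
#' @return An object of class `"rank_frequency"`: a data frame with columns
#'   `rank` and `freq` (and `label` when supplied), plus attributes `M`
#'   and `T`.
#' @examples
#' rank_frequency(c(2, 5, 1))
#' @export
rank_frequency <- function(freqs, labels = NULL) {
  stopifnot(is.numeric(freqs))
  if (length(freqs) == 0 || any(!is.finite(freqs)) || any(freqs <= 0)) {
    stop("`freqs` must be a non-empty vector of positive counts", call. = FALSE)
  }
  ord <- if (is.null(labels)) {
    order(-freqs)
  } else {
    stopifnot(length(labels) == length(freqs))
    order(-freqs, as.character(labels))
  }
  tab <- data.frame(rank = seq_along(freqs), freq = freqs[ord])
  if (!is.null(labels)) tab$label <- as.character(labels)[ord]
  structure(tab,
            M = length(freqs), T = sum(freqs),
            class = c("rank_frequency", "data.frame"))
}

#' @export
print.rank_frequency <- function(x, ...) {
  cat(sprintf("Rank-frequency table: M = %d distinct elements, T = %s occurrences\n",
              attr(x, "M"), format(attr(x, "T"))))
  print.data.frame(head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("... %d more ranks\n", nrow(x) - 10))
  invisible(x)
}
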