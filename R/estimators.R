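## Exponent estimators and event-stream plumbing.

#' Construct an event stream
#'
#' An ordered sequence of occurrences of element identifiers (words, tags,
#' country codes, article ids, ...). Prefix counts of an event stream define
#' the empirical growth curve `N(t)`.
#'
#' @param events Atomic vector of identifiers; coerced to character.
#' @return An object of class `"event_stream"` (a character vector).
#' @export
event_stream <- function(events) {
  ev <- as.character(events)
  if (length(ev) == 0) stop("event stream must contain at least one event", call. = FALSE)
  if (anyNA(ev) || any(!nzchar(ev))) {
    stop("event identifiers must be non-empty and non-missing", call. = FALSE)
  }
  structure(ev, class = "event_stream")
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("Event stream: %d events, %d distinct\n",
              length(x), length(unique(unclass(x)))))
  invisible(x)
}

#' Rank-frequency table of an event stream
#'
#' Counts occurrences of each distinct identifier and sorts them in
#' non-increasing order; frequency ties are broken by lexicographic order
#' of the identifier so the result is deterministic.
#'
#' @param stream An [event_stream()] (or a vector coercible to one).
#' @return A [rank_frequency()] table with the identifiers in `label`.
#' @examples
#' rank_frequency_from_stream(c("a", "b", "a", "c"))
#' @export
rank_frequency_from_stream <- function(stream) {
  ev <- unclass(event_stream(stream))
  cnt <- table(ev)
  rank_frequency(as.integer(cnt), labels = names(cnt))
}

#' Empirical growth curve of an event stream
#'
#' `N(t)` = number of distinct identifiers among the first `t` events,
#' recorded either at every event or at log-spaced checkpoints.
#'
#' @param stream An [event_stream()] (or a vector coercible to one).
#' @param checkpoints `"every"` to record at every event, or a single
#'   integer: the number of log-spaced checkpoints (deduplicated, so the
#'   result may hold fewer rows).
#' @return An object of class `"growth_curve"`: a data frame with integer
#'   columns `t` and `N`.
#' @examples
#' growth_curve_from_stream(c("a", "b", "a", "c"))  # N = 1 2 2 3
#' @export
growth_curve_from_stream <- function(stream, checkpoints = "every") {
  ev <- unclass(event_stream(stream))
  N <- cumsum(!duplicated(ev))
  t <- seq_along(ev)
  if (!identical(checkpoints, "every")) {
    stopifnot(is.numeric(checkpoints), length(checkpoints) == 1, checkpoints >= 2)
    keep <- unique(round(exp(seq(0, log(length(ev)), length.out = checkpoints))))
    t <- t[keep]
    N <- N[keep]
  }
  structure(data.frame(t = t, N = N), class = c("growth_curve", "data.frame"))
}

#' Discrete power-law maximum-likelihood fit of the Zipf exponent
#'
#' Fits the frequency-density exponent \eqn{\beta} of
#' \eqn{p(z) \propto z^{-\beta}} to the frequencies at or above `z_min` by
#' the continuous-approximation maximum-likelihood estimator
#' \deqn{\hat\beta = 1 + n \Big/ \sum_i \log\frac{z_i}{z_{min} - 1/2},}
#' and reports the corresponding rank exponent
#' \eqn{\hat\alpha = 1/(\hat\beta - 1)}. With `z_min = "auto"` the cutoff
#' is chosen by Kolmogorov-Smirnov minimization over candidate cutoffs
#' (the standard power-law fitting recipe), which removes the bias the
#' fixed `z_min = 1` estimator suffers when the small-frequency end of the
#' distribution bends away from a pure power law.
#'
#' @param table A [rank_frequency()] table, or a bare vector of positive
#'   integer frequencies.
#' @param z_min Smallest frequency included in the fit (positive integer),
#'   or `"auto"` for KS-minimizing selection (candidate cutoffs keep at
#'   least `min_tail` points).
#' @param min_tail Minimum tail size retained during automatic cutoff
#'   selection.
#' @return An object of class `"zipf_fit"`: a list with `alpha_hat`,
#'   `beta_hat`, `z_min`, `n_tail` and `ks` (the tail KS distance).
#' @examples
#' fit_zipf_mle(c(1, 1, 2, 3, 5))  # beta_hat ~ 1.728, alpha_hat ~ 1.373
#' @export
fit_zipf_mle <- function(table, z_min = 1, min_tail = 50) {
  z <- if (inherits(table, "rank_frequency")) table$freq else as.numeric(table)
  if (any(!is.finite(z)) || any(z < 1)) {
    stop("frequencies must be finite and >= 1", call. = FALSE)
  }
  if (identical(z_min, "auto")) {
    cand <- sort(unique(z))
    best <- NULL
    for (zm in cand) {
      n <- sum(z >= zm)
      if (n < max(2, min_tail)) break
      f <- .mle_at(z, zm)
      if (is.null(best) || f$ks < best$ks) best <- f
    }
    if (is.null(best)) best <- .mle_at(z, min(z))  # tiny samples: no selection
    fit <- best
  } else {
    stopifnot(is.numeric(z_min), length(z_min) == 1, z_min >= 1)
    if (sum(z >= z_min) < 2) {
      stop("fewer than 2 frequencies at or above `z_min`", call. = FALSE)
    }
    fit <- .mle_at(z, z_min)
  }
  structure(fit, class = "zipf_fit")
}

.mle_at <- function(z, zm) {
  zt <- z[z >= zm]
  n <- length(zt)
  beta <- 1 + n / sum(log(zt / (zm - 0.5)))
  zs <- sort(zt)
  ks <- max(abs((seq_len(n)) / n - (1 - (zs / zm)^(1 - beta))))
  list(alpha_hat = 1 / (beta - 1), beta_hat = beta,
       z_min = zm, n_tail = n, ks = ks)
}

#' @export
print.zipf_fit <- function(x, ...) {
  cat(sprintf("Zipf MLE fit: alpha_hat = %.4f (beta_hat = %.4f), z_min = %g, n_tail = %d\n",
              x$alpha_hat, x$beta_hat, x$z_min, x$n_tail))
  invisible(x)
}

#' Least-squares fit of the Heaps exponent
#'
#' Ordinary least squares of `log N` on `log t` over the points of a
#' growth curve, optionally restricted to a range of `t`.
#'
#' @param curve A [growth_curve_from_stream()] result, a
#'   [relation_curve()], or any data frame with columns `t` and `N`.
#' @param fit_range Optional numeric `c(t_lo, t_hi)`; default: the full
#'   curve.
#' @return An object of class `"heaps_fit"`: a list with `lambda_hat`,
#'   `intercept`, `fit_range`, `r_squared` and `n_points`.
#' @examples
#' fit_heaps_lsq(data.frame(t = c(10, 100, 1000), N = c(10, 100, 1000)^0.8))
#' @export
fit_heaps_lsq <- function(curve, fit_range = NULL) {
  stopifnot(is.data.frame(curve), all(c("t", "N") %in% names(curve)))
  t <- curve$t
  N <- curve$N
  if (any(N <= 0) || any(t <= 0)) {
    stop("growth curve values must be positive", call. = FALSE)
  }
  if (!is.null(fit_range)) {
    stopifnot(length(fit_range) == 2, fit_range[1] < fit_range[2])
    keep <- t >= fit_range[1] & t <= fit_range[2]
    t <- t[keep]
    N <- N[keep]
  }
  if (length(unique(t)) < 3) {
    stop("need at least 3 distinct t values in the fit range", call. = FALSE)
  }
  lx <- log(t)
  ly <- log(N)
  slope <- stats::cov(lx, ly) / var(lx)
  structure(list(lambda_hat = slope,
                 intercept = mean(ly) - slope * mean(lx),
                 fit_range = c(min(t), max(t)),
                 r_squared = if (var(ly) == 0) 1 else stats::cor(lx, ly)^2,
                 n_points = length(lx)),
            class = "heaps_fit")
}

#' @export
print.heaps_fit <- function(x, ...) {
  cat(sprintf("Heaps fit: lambda_hat = %.4f (R^2 = %.4f, %d points, t in [%g, %g])\n",
              x$lambda_hat, x$r_squared, x$n_points, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Event stream implied by a wide cumulative-count table
#'
#' Converts a surveillance-style table (rows = dates in chronological
#' order, columns = regions, cells = cumulative confirmed counts) into the
#' event stream whose prefix statistics reproduce the recorded totals: for
#' each date, every region emits one event per newly confirmed case.
#' Within a date, regions are emitted in lexicographic order, which is
#' deterministic and does not affect the curve at date boundaries.
#'
#' @param counts A data frame or matrix of non-decreasing cumulative counts
#'   with regions as column names (a first column of dates is carried as
#'   row labels if non-numeric).
#' @return An [event_stream()] of region identifiers whose length equals
#'   the final total cumulative count.
#' @examples
#' cumulative_counts_to_stream(data.frame(A = c(2, 3), B = c(0, 1)))
#' @export
cumulative_counts_to_stream <- function(counts) {
  counts <- as.data.frame(counts)
  if (ncol(counts) >= 1 && !is.numeric(counts[[1]])) {
    rownames(counts) <- as.character(counts[[1]])
    counts <- counts[, -1, drop = FALSE]
  }
  if (ncol(counts) == 0) stop("no region columns found", call. = FALSE)
  m <- as.matrix(counts)
  if (!is.numeric(m) || anyNA(m) || any(m < 0) || any(m != floor(m))) {
    stop("cumulative counts must be non-negative integers", call. = FALSE)
  }
  regions <- colnames(m)
  if (is.null(regions)) regions <- sprintf("region%d", seq_len(ncol(m)))
  inc <- diff(rbind(0, m))
  if (any(inc < 0)) {
    bad <- which(inc < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("cumulative count decreases at row %d, column '%s'",
                 bad[1], regions[bad[2]]), call. = FALSE)
  }
  ord <- order(regions)
  ev <- unlist(lapply(seq_len(nrow(m)), function(i) {
    rep(regions[ord], inc[i, ord])
  }), use.names = FALSE)
  event_stream(ev)
}

#' Tokenize plain text into an event stream
#'
#' Unicode-aware lowercasing followed by splitting on any run of
#' non-letter characters; empty tokens are dropped.
#'
#' @param text Character vector of lines.
#' @return Character vector of tokens (not yet an [event_stream()]).
#' @export
tokenize_text <- function(text) {
  toks <- unlist(strsplit(tolower(text), "[^\\p{L}]+", perl = TRUE), use.names = FALSE)
  toks[nzchar(toks)]
}
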