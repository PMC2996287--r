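## Rank-driven stochastic occurrence model and synthetic fixtures.
##
## At every time step the candidate pool is ranked by occurrence count in
## descending order (ties in random order) and the element at rank r occurs
## with probability proportional to a fixed rank profile. A pure power-law
## profile r^(-alpha) reproduces Zipf's law with exponent alpha and,
## derivatively, Heaps' growth of the number of distinct elements.

## run the process for a given step-probability profile over ranks 1..pool
.run_rank_process <- function(profile, steps, pool, seed = NULL) {
  stopifnot(steps >= 1, pool >= 1, length(profile) == pool, all(profile >= 0))
  if (!is.null(seed)) set.seed(seed)
  ranks <- sample.int(pool, steps, replace = TRUE, prob = profile)
  idx <- .rank_process(as.integer(ranks), as.integer(pool))
  ids <- sprintf("e%06d", idx)
  stream <- event_stream(ids)
  list(stream = stream,
       curve = growth_curve_from_stream(stream),
       table = rank_frequency_from_stream(stream))
}

.sim_result <- function(run, config) {
  structure(c(run, list(config = config)), class = "zipf_simulation")
}

#' @export
print.zipf_simulation <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Rank-driven simulation (%s mode): %d steps, pool %d, final N = %d\n",
              cfg$mode, cfg$steps, cfg$pool, attr(x$table, "M")))
  invisible(x)
}

#' Simulate a rank-driven occurrence stream with a Zipf profile
#'
#' The stochastic counterpart of the analytical finite-size relation: at
#' each of `steps` time steps, the `pool` candidate elements are ranked by
#' current occurrence count (descending, ties randomly ordered) and the
#' element at rank `r` occurs with probability proportional to
#' \eqn{r^{-\alpha}}. The pool defaults to `steps`, the largest number of
#' distinct elements that could possibly occur.
#'
#' @param alpha Rank exponent of the step probabilities, >= 0.
#' @param steps Number of time steps (total occurrences), >= 1.
#' @param pool Number of candidate elements, >= 1.
#' @param seed Optional integer seed; identical seeds give identical
#'   streams.
#' @return An object of class `"zipf_simulation"`: a list with `stream`
#'   (the [event_stream()]), `curve` (every-event [growth_curve_from_stream()]),
#'   `table` (final [rank_frequency()]) and `config`.
#' @examples
#' sim <- simulate_zipf_stream(1.5, steps = 2000, seed = 1)
#' fit_heaps_lsq(sim$curve)
#' @export
simulate_zipf_stream <- function(alpha, steps, pool = steps, seed = NULL) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, is.finite(alpha), alpha >= 0)
  profile <- seq_len(pool)^(-alpha)
  run <- .run_rank_process(profile, steps, pool, seed)
  .sim_result(run, list(mode = "zipf", alpha = alpha, steps = steps,
                        pool = pool, seed = seed))
}

## rank profile implied by a frequency density: z(r) is the (1 - r/pool)
## quantile of the discretized density, i.e. the survival-function inverse
.rank_profile_from_density <- function(density_fun, z_max, pool) {
  z <- seq_len(z_max)
  q <- density_fun(z)
  q <- q / sum(q)
  surv <- rev(cumsum(rev(q)))          # P(Z >= z), non-increasing in z
  p <- seq_len(pool) / pool
  ## z(r) = largest z with surv(z) >= r/pool; -surv is ascending, so the
  ## count of ranks with surv >= p is findInterval(-p, -surv)
  zr <- pmax(findInterval(-p, -surv), 1L)
  as.numeric(zr)
}

#' Simulate with a power-law profile damped by an exponential cutoff
#'
#' Builds the rank-based frequency profile implied by the density
#' \eqn{p(z) \propto z^{-\beta} e^{-z/z_c}} (via the survival-function
#' inverse on a discretized frequency range) and runs the rank-driven
#' process with step probabilities proportional to that profile. As
#' \eqn{z_c \to \infty} this recovers the pure Zipf simulation with
#' \eqn{\alpha = 1/(\beta - 1)}; strengthening the cutoff (smaller `z_c`)
#' raises the effective Heaps exponent while log-log linearity of the
#' growth curve persists.
#'
#' @param beta Density exponent, > 1.
#' @param z_c Cutoff scale, > 0.
#' @inheritParams simulate_zipf_stream
#' @param z_max Upper end of the discretized frequency range; the default
#'   `max(50 * z_c, 1e4)` leaves negligible tail mass beyond it.
#' @return A `"zipf_simulation"` object (see [simulate_zipf_stream()]).
#' @export
simulate_cutoff_stream <- function(beta, z_c, steps, pool = steps, seed = NULL,
                                   z_max = NULL) {
  stopifnot(is.finite(beta), beta > 1, is.finite(z_c), z_c > 0)
  if (is.null(z_max)) z_max <- ceiling(max(50 * z_c, 1e4))
  profile <- .rank_profile_from_density(function(z) z^(-beta) * exp(-z / z_c),
                                        z_max, pool)
  run <- .run_rank_process(profile, steps, pool, seed)
  .sim_result(run, list(mode = "cutoff", beta = beta, z_c = z_c, steps = steps,
                        pool = pool, seed = seed))
}

#' Simulate with a purely exponential rank profile
#'
#' Step probabilities proportional to \eqn{e^{-\mathrm{rate}\, r}}. Unlike
#' the power-law profiles, the resulting growth of distinct elements is
#' almost linear early on and then bends away from any power law.
#'
#' @param rate Decay rate of the rank profile, > 0.
#' @inheritParams simulate_zipf_stream
#' @return A `"zipf_simulation"` object (see [simulate_zipf_stream()]).
#' @export
simulate_exponential_stream <- function(rate, steps, pool = steps, seed = NULL) {
  stopifnot(is.finite(rate), rate > 0)
  profile <- exp(-rate * (seq_len(pool) - 1))  # shifted so profile[1] = 1
  run <- .run_rank_process(profile, steps, pool, seed)
  .sim_result(run, list(mode = "exponential", rate = rate, steps = steps,
                        pool = pool, seed = seed))
}

#' Write a reproducible synthetic data fixture to disk
#'
#' Generates a simulation of the requested kind and writes its artifacts
#' as plain-text files under `dir`: the event stream
#' (`<prefix>.events`, one identifier per line, or whitespace-tokenized
#' lines for `"text-like"`), the final rank-frequency table
#' (`<prefix>_rankfreq.tsv`), the growth curve (`<prefix>_growth.tsv`), a
#' JSON manifest (`<prefix>_manifest.json`), and for `"outbreak-like"` a
#' wide cumulative CSV (`<prefix>_cumulative.csv`) whose implied stream
#' reproduces the generator's stream at date boundaries. All outputs are
#' reproducible from `seed`.
#'
#' @param kind One of `"zipf"`, `"cutoff"`, `"exponential"`, `"text-like"`,
#'   `"outbreak-like"`.
#' @param params Named list of generator parameters (`alpha`, `beta`,
#'   `z_c`, `rate`, `steps`, `pool`, and `n_dates`/`n_regions` for
#'   `"outbreak-like"`). Missing entries take the generator defaults.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, a named character vector of the files written.
#' @export
make_fixture <- function(kind = c("zipf", "cutoff", "exponential",
                                  "text-like", "outbreak-like"),
                         params = list(), seed = 1,
                         dir = ".", prefix = kind) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  steps <- p("steps", 1e4)
  pool <- p("pool", steps)
  sim <- switch(kind,
    "zipf" = ,
    "text-like" = simulate_zipf_stream(p("alpha", 1), steps, pool, seed),
    "outbreak-like" = simulate_zipf_stream(p("alpha", 3), steps,
                                           p("pool", p("n_regions", 50)), seed),
    "cutoff" = simulate_cutoff_stream(p("beta", 2.5), p("z_c", 100), steps, pool, seed),
    "exponential" = simulate_exponential_stream(p("rate", 0.01), steps, pool, seed))
  path <- function(suffix) file.path(dir, paste0(prefix, suffix))
  files <- c(stream = path(".events"),
             rankfreq = path("_rankfreq.tsv"),
             growth = path("_growth.tsv"),
             manifest = path("_manifest.json"))
  if (kind == "text-like") {
    ## whitespace-tokenized lines of 12 "words"; identifiers are re-encoded
    ## with letters only so that tokenization round-trips them
    ev <- chartr("0123456789", "abcdefghij", unclass(sim$stream))
    lines <- vapply(split(ev, (seq_along(ev) - 1) %/% 12),
                    paste, character(1), collapse = " ")
    writeLines(lines, files[["stream"]])
  } else {
    writeLines(unclass(sim$stream), files[["stream"]])
  }
  write_rank_frequency(sim$table, files[["rankfreq"]])
  write_growth_curve(growth_curve_from_stream(sim$stream, checkpoints = 1000),
                     files[["growth"]])
  if (kind == "outbreak-like") {
    files <- c(files, cumulative = path("_cumulative.csv"))
    ev <- unclass(sim$stream)
    n_dates <- p("n_dates", 20)
    day <- ceiling(seq_along(ev) / (length(ev) / n_dates))
    regions <- sort(unique(ev))
    daily <- table(factor(day, levels = seq_len(n_dates)),
                   factor(ev, levels = regions))
    cum <- apply(daily, 2, cumsum)   # dates x regions
    wide <- data.frame(date = format(as.Date("2009-04-26") + seq_len(n_dates) - 1),
                       cum, check.names = FALSE)
    colnames(wide) <- c("date", regions)
    utils::write.csv(wide, files[["cumulative"]], row.names = FALSE, quote = FALSE)
  }
  manifest <- c(list(kind = kind, seed = seed), sim$config)
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(files)
}
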