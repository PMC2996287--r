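## Batch evaluation of the finite-size and asymptotic Heaps exponents for
## a list of (alpha, T) pairs, mirroring the reference-survey schema:
## label, T, M, alpha, lambda_asym, lambda_num, lambda_emp.

#' Reference survey of 35 empirical systems
#'
#' The packaged reference table of empirical statistics for 35 systems
#' (word occurrences in nine books, keyword occurrences in 24 scientific
#' journals, country-level H1N1 confirmed-case records, and PNAS citation
#' records): total size `T`, number of distinct elements `M`, the
#' maximum-likelihood Zipf exponent `alpha`, and the asymptotic, numeric
#' and empirical Heaps exponents as printed in the survey.
#'
#' @return A data frame with columns `no`, `label`, `T`, `M`, `alpha`,
#'   `lambda_asym`, `lambda_num`, `lambda_emp`.
#' @export
table1_reference <- function() {
  path <- system.file("extdata", "table1.tsv", package = "zipfheaps",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

## round-half-even to the printed precision: 3 decimals, 2 for small systems
.lambda_digits <- function(size) if (size < 1e4) 2L else 3L

#' Format a Heaps exponent the way the reference table prints it
#'
#' Round-half-even to 3 decimals (2 when `size < 1e4`, where the effective
#' precision is only two digits); values that round to 1 print as `"1"`.
#'
#' @param lambda Exponent value(s).
#' @param size System size(s), used to pick the printed precision.
#' @return Character vector.
#' @export
format_lambda <- function(lambda, size) {
  digits <- vapply(size, .lambda_digits, integer(1))
  out <- character(length(lambda))
  for (i in seq_along(lambda)) {
    r <- round(lambda[i], digits[i])
    out[i] <- if (r == 1) "1" else formatC(r, format = "f", digits = digits[i])
  }
  out
}

#' Write one formatted result row
#'
#' Emits a tab-separated row `label T M alpha lambda_asym lambda_num
#' [lambda_emp]`; the empirical column is omitted when absent.
#'
#' @param record Named list or one-row data frame with fields `label`,
#'   `T`, `M` (optional), `alpha`, `lambda_asym`, `lambda_num` and
#'   optionally `lambda_emp`.
#' @param con Connection or file path ("" prints to stdout).
#' @return The formatted row, invisibly.
#' @export
write_table1_row <- function(record, con = "") {
  record <- as.list(record)
  size <- as.numeric(record$T)
  fields <- c(as.character(record$label),
              format(size, scientific = FALSE, trim = TRUE),
              if (!is.null(record$M)) format(record$M, scientific = FALSE, trim = TRUE),
              format(record$alpha),
              format_lambda(as.numeric(record$lambda_asym), size),
              format_lambda(as.numeric(record$lambda_num), size),
              if (!is.null(record$lambda_emp) && is.finite(as.numeric(record$lambda_emp)))
                format_lambda(as.numeric(record$lambda_emp), size))
  row <- paste(fields, collapse = "\t")
  writeLines(row, con = con)
  invisible(row)
}

#' Recompute predicted Heaps exponents for a list of (alpha, T) pairs
#'
#' For every row of `config`, computes the asymptotic Heaps exponent
#' ([asymptotic_heaps()]) and the finite-size numeric exponent
#' ([heaps_exponent_numeric()]). When an empirical exponent `lambda_emp`
#' is supplied, each row also records the absolute errors of both
#' predictions and which one lies closer; the attribute
#' `"numeric_beats_asymptotic"` counts the rows where the finite-size
#' prediction wins.
#'
#' @param config Data frame with columns `alpha` and `T` (and optionally
#'   `label`, `lambda_emp`). Defaults to [table1_reference()].
#' @param grid_size Passed to [heaps_exponent_numeric()].
#' @return `config` augmented with `lambda_asym`, `lambda_num` and, when
#'   `lambda_emp` is present, `err_num`, `err_asym`, `numeric_wins`.
#'   Invalid rows (non-positive `alpha` or `T < 10`) are dropped with a
#'   warning.
#' @examples
#' run_table1_suite(data.frame(label = "row1", alpha = 1.323, T = 206779))
#' @export
run_table1_suite <- function(config = table1_reference(), grid_size = 1e5) {
  stopifnot(is.data.frame(config))
  if (nrow(config) == 0) {
    return(structure(config, numeric_beats_asymptotic = 0L))
  }
  stopifnot(all(c("alpha", "T") %in% names(config)))
  ok <- is.finite(config$alpha) & config$alpha > 0 &
    is.finite(config$T) & config$T >= 10
  if (any(!ok)) {
    warning(sprintf("skipping %d invalid row(s)", sum(!ok)), call. = FALSE)
    config <- config[ok, , drop = FALSE]
  }
  config$lambda_asym <- asymptotic_heaps(config$alpha)
  config$lambda_num <- mapply(heaps_exponent_numeric,
                              config$alpha, config$T,
                              MoreArgs = list(grid_size = grid_size))
  wins <- NA_integer_
  if ("lambda_emp" %in% names(config)) {
    config$err_num <- abs(config$lambda_num - config$lambda_emp)
    config$err_asym <- abs(config$lambda_asym - config$lambda_emp)
    config$numeric_wins <- config$err_num < config$err_asym
    wins <- sum(config$numeric_wins)
  }
  structure(config, numeric_beats_asymptotic = wins)
}
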