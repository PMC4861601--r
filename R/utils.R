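#' @keywords internal
"_PACKAGE"

# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_data <- function(...) stop(..., call. = FALSE)

check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop_data(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

#' Signed mean of the k phenotypes largest in absolute value
#'
#' Selection is by absolute value, but the mean keeps the sign, so a
#' consistently sensitizing gene gets a negative effect size and its most
#' active guides still normalize to activity ~ +1.
#'
#' @param x numeric vector of phenotypes.
#' @param k number of strongest values to average (default 3).
#' @return Signed mean of the `k` values of `x` with largest `|x|`.
#' @export
strongest_mean <- function(x, k = 3L) {
  x <- x[!is.na(x)]
  if (length(x) < k)
    stop_data("strongest_mean() needs at least ", k, " values, got ", length(x))
  ord <- order(abs(x), decreasing = TRUE)
  mean(x[ord[seq_len(k)]])
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
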