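# Per-sgRNA activity vs target-site occupancy: binned rank tests and
# multi-feature linear models with residual correction.

#' Two-tailed Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact p-value when the smaller sample has at most 8 observations and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction. The returned p is clamped into (0, 1].
#'
#' @param x,y numeric samples (both nonempty).
#' @return Two-tailed p-value.
#' @export
mann_whitney_two_tailed <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop_data("empty sample")
  exact <- min(length(x), length(y)) <= 8 && !anyDuplicated(c(x, y))
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value)
  min(max(p, .Machine$double.xmin), 1)
}

#' Bin sgRNAs by target-site occupancy and test each bin against zero
#'
#' The zero bin holds exactly the observations with occupancy 0; the
#' remaining observations fall into right-closed bins `(k*w, (k+1)*w]`
#' labeled by their lower edge. Each bin's activities are compared to the
#' zero bin by a two-tailed Mann-Whitney test (p omitted for bins with
#' fewer than 2 observations). Whiskers follow the Tukey convention
#' (most extreme point within 1.5 IQR of the quartiles).
#'
#' @param activity,occupancy aligned numeric vectors; occupancy must be
#'   nonnegative.
#' @param bin_width positive bin width (default 0.2).
#' @return data.frame of class `bin_association` with per-bin `label`,
#'   `bin_min`, `n`, `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `mw_p`. Attribute `zero_bin_empty` flags an undefined reference bin.
#' @export
bin_by_occupancy <- function(activity, occupancy, bin_width = 0.2) {
  if (length(activity) != length(occupancy))
    stop_data("activity and occupancy must be aligned")
  keep <- !is.na(activity) & !is.na(occupancy)
  activity <- activity[keep]
  occupancy <- occupancy[keep]
  if (any(occupancy < 0)) stop_data("occupancy must be nonnegative")
  if (bin_width <= 0) stop_data("bin_width must be positive")

  k <- ifelse(occupancy == 0, 0L, ceiling(occupancy / bin_width))
  bins <- sort(unique(k))
  zero_act <- activity[k == 0L]
  zero_empty <- length(zero_act) == 0
  if (zero_empty)
    warning("zero-occupancy bin is empty; per-bin tests are undefined")

  rows <- lapply(bins, function(b) {
    a <- activity[k == b]
    q <- stats::quantile(a, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    wlo <- min(a[a >= q[1] - 1.5 * iqr])
    whi <- max(a[a <= q[3] + 1.5 * iqr])
    p <- if (b == 0L || zero_empty || length(a) < 2) NA_real_
         else mann_whitney_two_tailed(a, zero_act)
    data.frame(label = if (b == 0L) "=0.0"
               else sprintf(">%.8g", (b - 1) * bin_width),
               bin_min = (max(b - 1, 0)) * bin_width,
               n = length(a), median = q[2], q1 = q[1], q3 = q[3],
               whisker_lo = wlo, whisker_hi = whi, mw_p = p,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("bin_association", "data.frame"),
            bin_width = bin_width, zero_bin_empty = zero_empty)
}

#' Ordinary least-squares fit of activity on guide features
#'
#' Fits activity on any subset of the feature columns (typically target-site
#' occupancy, sgRNA length, and a sequence score) by OLS with intercept.
#' `r2` is the squared Pearson correlation between fitted values and the
#' response, which for OLS with intercept equals the coefficient of
#' determination. Rows with a missing selected feature are dropped listwise
#' and counted.
#'
#' @param data data.frame containing the feature and response columns.
#' @param features character vector of feature column names.
#' @param response response column name (default `"activity"`).
#' @return List of class `guide_fit`: `features`, `coefficients` (with
#'   intercept), `se` (standard errors), `r2`, `fitted`, `residuals`,
#'   `n`, `n_dropped`, `rank_deficient`.
#' @export
fit_linear <- function(data, features, response = "activity") {
  check_cols(data, c(features, response), "regression data")
  df <- data[, c(features, response), drop = FALSE]
  cc <- stats::complete.cases(df)
  n_dropped <- sum(!cc)
  if (n_dropped > 0)
    message("fit_linear: dropped ", n_dropped, " row(s) with missing features")
  df <- df[cc, , drop = FALSE]
  if (nrow(df) < length(features) + 2)
    stop_data("need at least p + 2 complete rows to fit ", length(features),
              " feature(s)")
  fit <- stats::lm(stats::reformulate(features, response), data = df)
  rank_def <- anyNA(stats::coef(fit))
  if (rank_def)
    warning("rank-deficient design; aliased coefficients dropped")
  fv <- stats::fitted(fit)
  y <- df[[response]]
  r2 <- if (stats::sd(fv) == 0 || stats::sd(y) == 0) 0
        else stats::cor(fv, y)^2
  se <- rep(NA_real_, length(stats::coef(fit)))
  sm <- summary(fit)$coefficients
  se[match(rownames(sm), names(stats::coef(fit)))] <- sm[, "Std. Error"]
  names(se) <- names(stats::coef(fit))
  structure(list(features = features, coefficients = stats::coef(fit),
                 se = se, r2 = r2, fitted = fv,
                 residuals = stats::resid(fit), n = nrow(df),
                 n_dropped = n_dropped, rank_deficient = rank_def),
            class = "guide_fit")
}

#' @export
print.guide_fit <- function(x, ...) {
  cat("guide_fit on {", paste(x$features, collapse = ", "), "}: r2 =",
      format(x$r2, digits = 4), "n =", x$n, "\n")
  print(x$coefficients)
  invisible(x)
}

#' Correct activity scores for sequence and length features
#'
#' Subtracts the OLS prediction from the combined sequence-score + length
#' fit, leaving the component of activity not explained by those features.
#' The residuals have zero mean and exactly zero sample correlation with
#' both correcting features.
#'
#' @param activity numeric response.
#' @param seq_score,length aligned numeric feature vectors.
#' @return Numeric vector aligned with the input (`NA` where a feature was
#'   missing), with attribute `n_dropped`.
#' @export
correct_activity <- function(activity, seq_score, length) {
  df <- data.frame(activity = activity, seq_score = seq_score,
                   length = length)
  fit <- fit_linear(df, c("seq_score", "length"))
  out <- rep(NA_real_, nrow(df))
  out[stats::complete.cases(df)] <- fit$residuals
  structure(out, n_dropped = fit$n_dropped)
}
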