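# TSS-relative windowed activity profiles, zero-phase Butterworth smoothing,
# and peak/trough quantification of the ~190 bp periodicity.

#' Windowed mean activity relative to the TSS
#'
#' The profile value at relative position d is the mean activity of all
#' sgRNAs whose TSS-relative position falls in the half-open window
#' `[d - window/2, d + window/2)`, so each sgRNA contributes to exactly
#' `window` centers. Positions supported by fewer than `min_n` sgRNAs are
#' reported as missing.
#'
#' @param activities data.frame with columns `rel_pos` (signed bp to the TSS,
#'   downstream positive) and `activity`.
#' @param window window width in bp (default 50).
#' @param min_n minimum sgRNAs per window for the mean to be reported
#'   (default 10).
#' @param range optional length-2 integer vector of profile positions;
#'   defaults to the span of the data.
#' @return data.frame of class `activity_profile` with columns `rel_pos`,
#'   `value` (NA where `n_sgrnas < min_n`), `n_sgrnas`.
#' @export
windowed_profile <- function(activities, window = 50L, min_n = 10L,
                             range = NULL) {
  check_cols(activities, c("rel_pos", "activity"), "activities")
  if (nrow(activities) == 0) stop_data("empty activity table")
  if (!all(is.finite(activities$activity))) stop_data("activities must be finite")
  if (window <= 0) stop_data("window must be positive")
  half <- window / 2
  if (is.null(range))
    range <- c(floor(min(activities$rel_pos)), ceiling(max(activities$rel_pos)))
  d <- seq(range[1], range[2])
  ord <- order(activities$rel_pos)
  xs <- activities$rel_pos[ord]
  cs <- c(0, cumsum(activities$activity[ord]))
  lo <- findInterval(d - half, xs, left.open = TRUE)  # count of xs <  d - half
  hi <- findInterval(d + half, xs, left.open = TRUE)  # count of xs <  d + half
  n <- hi - lo
  val <- (cs[hi + 1] - cs[lo + 1]) / n
  val[n < min_n] <- NA_real_
  structure(data.frame(rel_pos = d, value = val, n_sgrnas = n),
            class = c("activity_profile", "data.frame"),
            window = window, min_n = min_n)
}

# steady-state direct-form-I filter pass: previous inputs/outputs are taken
# as if the signal had been constant at x[1] forever
ss_filter <- function(b, a, x) {
  dc <- sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], length(b) - 1),
                            init.y = rep(x[1] * dc, length(a) - 1)))
}

# zero-phase (forward-backward) filtering with odd-reflection padding
zero_phase_filter <- function(b, a, x) {
  n <- length(x)
  padlen <- min(3L * max(length(a), length(b)), n - 1L)
  ext <- c(2 * x[1] - x[seq(padlen + 1, 2)], x,
           2 * x[n] - x[seq(n - 1, n - padlen)])
  y <- rev(ss_filter(b, a, ext))
  y <- rev(ss_filter(b, a, y))
  y[(padlen + 1):(padlen + n)]
}

#' Smooth a profile with a zero-phase low-pass Butterworth filter
#'
#' The filter is applied forward and backward so peak positions are not
#' shifted by phase distortion. The critical frequency `cutoff` is expressed
#' as a fraction of the Nyquist frequency at the profile's 1 bp sampling
#' (0.03 corresponds to a half-power period of ~67 bp, well below the
#' ~190 bp nucleosome repeat). Missing interior values are linearly
#' interpolated first and the ends are held at the nearest defined value.
#'
#' @param profile an [windowed_profile()] result (1 bp sampling).
#' @param order filter order (default 4).
#' @param cutoff critical frequency as a fraction of Nyquist (default 0.03).
#' @return The profile with an added `smoothed` column; the logical
#'   interpolation mask is attached as attribute `"interpolated"`.
#' @export
smooth_profile <- function(profile, order = 4L, cutoff = 0.03) {
  check_cols(profile, c("rel_pos", "value"), "profile")
  ok <- !is.na(profile$value)
  if (!any(ok)) stop_data("all profile values are missing")
  if (sum(ok) < 2) stop_data("profile has fewer than 2 defined values")
  n <- nrow(profile)
  if (n <= 3L * (order + 1L))
    stop_data("profile shorter than the filter warm-up length")
  v <- stats::approx(profile$rel_pos[ok], profile$value[ok],
                     xout = profile$rel_pos, rule = 2)$y
  bf <- signal::butter(order, cutoff)
  profile$smoothed <- zero_phase_filter(bf$b, bf$a, v)
  attr(profile, "interpolated") <- !ok
  attr(profile, "window") <- attr(profile, "window") %||% 50L
  profile
}

# local extrema by strict sign change of the first difference over runs of
# equal values; plateaus collapse to their central position (floor of midpoint)
local_extrema <- function(x) {
  r <- rle(x)
  m <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  if (m < 3) return(list(max = integer(0), min = integer(0)))
  i <- 2:(m - 1)
  dprev <- r$values[i] - r$values[i - 1]
  dnext <- r$values[i + 1] - r$values[i]
  center <- (starts + ends) %/% 2L
  list(max = center[i][dprev > 0 & dnext < 0],
       min = center[i][dprev < 0 & dnext > 0])
}

#' Peaks, troughs, and amplitudes of a smoothed activity profile
#'
#' Peak 0 is the local maximum closest to the TSS (downstream tie-break);
#' subsequent peaks are the successive local maxima downstream of peak 0.
#' Trough k is the first local minimum downstream of peak k, and amplitude k
#' is `peak_k value - trough_k value`. Peaks falling inside an interpolated
#' stretch longer than the profile's window are not reported.
#'
#' @param profile a [smooth_profile()] result (the `smoothed` column is used;
#'   falls back to `value` when absent, which must then have no interior NA).
#' @return List of class `periodicity_result` with data.frames `peaks`
#'   (`rel_pos`, `value`) and `troughs`, and numeric `amplitudes` (NA for a
#'   peak without a downstream trough).
#' @export
find_peaks_troughs <- function(profile) {
  x <- profile$smoothed %||% profile$value
  if (anyNA(x)) stop_data("profile has missing values; smooth it first")
  rel <- profile$rel_pos
  ext <- local_extrema(x)
  if (length(ext$max) == 0) stop_data("no local maximum in profile")

  interp <- attr(profile, "interpolated")
  win <- attr(profile, "window") %||% 50L
  if (!is.null(interp) && any(interp)) {
    r <- rle(interp)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    bad <- r$values & r$lengths > win
    in_bad <- rep(FALSE, length(x))
    for (j in which(bad)) in_bad[starts[j]:ends[j]] <- TRUE
    ext$max <- ext$max[!in_bad[ext$max]]
    if (length(ext$max) == 0) stop_data("no local maximum outside interpolated gaps")
  }

  rel_max <- rel[ext$max]
  i0 <- which(abs(rel_max) == min(abs(rel_max)))
  i0 <- i0[which.max(rel_max[i0])]                 # tie -> downstream
  keep <- which(rel_max >= rel_max[i0])
  peaks <- data.frame(rel_pos = rel_max[keep], value = x[ext$max][keep])
  peaks <- peaks[order(peaks$rel_pos), ]

  rel_min <- rel[ext$min]
  val_min <- x[ext$min]
  tr_pos <- tr_val <- rep(NA_real_, nrow(peaks))
  for (k in seq_len(nrow(peaks))) {
    ds <- which(rel_min > peaks$rel_pos[k])
    if (length(ds) > 0) {
      j <- ds[which.min(rel_min[ds])]
      tr_pos[k] <- rel_min[j]
      tr_val[k] <- val_min[j]
    }
  }
  has_tr <- !is.na(tr_pos)
  rownames(peaks) <- NULL
  structure(list(peaks = peaks,
                 troughs = data.frame(rel_pos = tr_pos[has_tr],
                                      value = tr_val[has_tr]),
                 amplitudes = peaks$value - tr_val),
            class = "periodicity_result")
}

#' @export
print.periodicity_result <- function(x, ...) {
  cat("periodicity_result:", nrow(x$peaks), "peak(s)\n")
  for (k in seq_len(nrow(x$peaks)))
    cat(sprintf("  peak%d at %+d bp (%.3f), amplitude %s\n", k - 1L,
                as.integer(x$peaks$rel_pos[k]), x$peaks$value[k],
                ifelse(is.na(x$amplitudes[k]), "NA",
                       sprintf("%.3f", x$amplitudes[k]))))
  invisible(x)
}

#' Median spacing between consecutive profile peaks
#'
#' @param result a [find_peaks_troughs()] result.
#' @return Median of the differences between consecutive peak positions
#'   (bp); NA with a warning when fewer than two peaks were found.
#' @export
peak_spacing <- function(result) {
  p <- result$peaks$rel_pos
  if (length(p) < 2) {
    warning("fewer than two peaks; spacing undefined")
    return(NA_real_)
  }
  stats::median(diff(p))
}

#' Group genes by expression level
#'
#' A gene's expression is the FPKM of its highest-expressed transcript;
#' genes are assigned to low / mid / high groups by two increasing
#' thresholds, with left-closed upper bins (a gene exactly at a threshold
#' goes to the higher group).
#'
#' @param fpkm data.frame with columns `gene` and `fpkm` (one row per
#'   transcript).
#' @param thresholds increasing numeric length-2 `(t1, t2)` in FPKM.
#' @return data.frame `gene`, `fpkm` (max over transcripts), `group`
#'   (factor low/mid/high), with `thresholds` attached as an attribute.
#' @export
group_by_expression <- function(fpkm, thresholds = c(2.7, 20)) {
  check_cols(fpkm, c("gene", "fpkm"), "FPKM table")
  if (any(fpkm$fpkm < 0)) stop_data("negative FPKM")
  if (length(thresholds) != 2 || diff(thresholds) <= 0)
    stop_data("thresholds must be two increasing values")
  mx <- tapply(fpkm$fpkm, fpkm$gene, max)
  grp <- cut(as.numeric(mx), breaks = c(-Inf, thresholds, Inf),
             labels = c("low", "mid", "high"), right = FALSE)
  structure(data.frame(gene = names(mx), fpkm = as.numeric(mx), group = grp,
                       stringsAsFactors = FALSE, row.names = NULL),
            thresholds = thresholds)
}
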