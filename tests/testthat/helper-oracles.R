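# Independent brute-force oracles, kept deliberately naive.

# Two-tailed Mann-Whitney p by full enumeration over all assignments of the
# pooled ranks to the first sample (valid for untied data).
mw_enum_p <- function(x, y) {
  n <- length(x)
  N <- n + length(y)
  r <- rank(c(x, y))
  stat <- function(idx) sum(r[idx]) - n * (n + 1) / 2
  u_obs <- stat(seq_len(n))
  center <- n * length(y) / 2
  sets <- utils::combn(N, n)
  us <- apply(sets, 2, stat)
  mean(abs(us - center) >= abs(u_obs - center))
}

# Per-base loop version of site_occupancy (zero policy).
brute_site_occupancy <- function(track, chrom, start, end) {
  acc <- 0
  for (p in start:(end - 1)) {
    v <- track_values(track, chrom, p)
    acc <- acc + if (is.na(v)) 0 else v
  }
  acc / (end - start)
}

# O(positions x sgRNAs) double loop version of windowed_profile.
brute_windowed <- function(activities, window, min_n, range) {
  d <- seq(range[1], range[2])
  val <- rep(NA_real_, length(d))
  n <- integer(length(d))
  for (i in seq_along(d)) {
    inw <- activities$rel_pos >= d[i] - window / 2 &
      activities$rel_pos < d[i] + window / 2
    n[i] <- sum(inw)
    if (n[i] >= min_n) val[i] <- mean(activities$activity[inw])
  }
  data.frame(rel_pos = d, value = val, n_sgrnas = n)
}

# constant-valued track over one interval, for hand-checkable fixtures
flat_track <- function(chrom = "chr1", start = 0, len = 100, value = 1) {
  signal_track(stats::setNames(
    list(list(offset = start, values = rep(value, len))), chrom))
}
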