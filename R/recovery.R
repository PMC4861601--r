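# One-call recovery analysis of a synthetic screen: the in-memory analogue
# of run_pipeline(), used to measure how well the scoring + profiling +
# association stages recover the generator's ground truth.

#' Score and profile one synthetic screen
#'
#' Generates a synthetic screen bundle, recovers phenotypes, hits and
#' activity scores, builds the TSS-relative windowed activity profile
#' (smoothed, with peak calling) and the TSS-relative occupancy profile,
#' and fits the activity-vs-features regressions.
#'
#' @param cfg a [synthetic_config()]; `cfg$seed` drives all randomness.
#' @param range profile range in bp relative to the TSS; defaults to the
#'   tiled span shrunk by half a window.
#' @param null_pseudogenes pseudo-genes for the effect-Z null (default
#'   10000, as in [gene_stats()]).
#' @param associate also compute per-site occupancy and the feature
#'   regressions (default TRUE; disable when only the profile-level
#'   quantities are needed).
#' @return List with the generated `bundle`, recovered `activities`,
#'   smoothed `profile`, `periodicity` result, `occupancy_profile`,
#'   `median_peak_spacing` (bp), `profile_anticorrelation` (Pearson r of
#'   windowed activity vs TSS-relative occupancy), `fits` (occupancy-only
#'   and all-feature regressions), and `truth_correlation` (recovered vs
#'   true activity).
#' @export
analyze_synthetic_screen <- function(cfg = synthetic_config(), range = NULL,
                                     null_pseudogenes = 10000L,
                                     associate = TRUE) {
  if (is.null(range))
    range <- c(-cfg$span_upstream + 50L, cfg$span_downstream - 50L)
  b <- generate_screen_data(cfg)
  nc <- b$library$sgrna_id[b$library$is_negctrl]
  phen <- compute_phenotypes(b$counts, nc, doublings = b$doublings)
  st <- gene_stats(phen, b$library, null_pseudogenes = null_pseudogenes,
                   seed = cfg$seed)
  hits <- call_hits(st)
  act <- activity_scores(phen, hits, b$library)
  rel <- sgrna_rel_pos(b$library, b$tss)
  act_rel <- merge(act, rel[, c("sgrna_id", "rel_pos")], by = "sgrna_id")
  prof <- smooth_profile(windowed_profile(act_rel, range = range))
  pk <- find_peaks_troughs(prof)
  occ_prof <- tss_relative_signal(b$track, b$tss, range)
  common <- merge(prof, occ_prof, by = "rel_pos")
  anticor <- stats::cor(common$value.x, common$value.y,
                        use = "complete.obs")
  fits <- NULL
  if (associate) {
    occ <- library_occupancy(b$track, b$library)
    adf <- merge(merge(act, occ, by = "sgrna_id"),
                 b$library[, c("sgrna_id", "protospacer_len", "seq_score")],
                 by = "sgrna_id")
    adf$length <- adf$protospacer_len + 3L
    fits <- list(occupancy = fit_linear(adf, "occupancy"),
                 all = fit_linear(adf, c("occupancy", "length", "seq_score")))
  }
  m <- merge(act, b$truth, by = "sgrna_id")
  list(bundle = b, activities = act, profile = prof, periodicity = pk,
       occupancy_profile = occ_prof,
       median_peak_spacing = peak_spacing(pk),
       profile_anticorrelation = anticor, fits = fits,
       truth_correlation = stats::cor(m$activity, m$activity_true))
}
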