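# End-to-end pipeline: score -> occupancy -> profile -> associate, driven by
# a single config, with a run manifest for traceability.

#' Pipeline configuration
#'
#' Bundles the input paths and every stage parameter. The defaults are the
#' pipeline's canonical constants: hit threshold 20, 50 bp windows with at
#' least 10 sgRNAs, order-4 Butterworth at 0.03 of Nyquist, occupancy bin
#' width 0.2.
#'
#' @param counts,library,track,tss,fpkm input file paths (`fpkm`,
#'   `doublings` optional).
#' @param out_dir output directory.
#' @param doublings optional doublings sidecar TSV path.
#' @param pseudocount RPM pseudocount for phenotypes.
#' @param threshold hit-score threshold (inclusive).
#' @param null_pseudogenes pseudo-genes for the effect Z null.
#' @param window,min_n profile window width and minimum guides per window.
#' @param filter_order,filter_cutoff Butterworth smoothing parameters.
#' @param bin_width occupancy bin width.
#' @param expression_thresholds FPKM thresholds `(t1, t2)` for low/mid/high.
#' @param range profile range in bp relative to the TSS.
#' @param missing_policy occupancy missing-base policy (`"zero"`/`"skip"`).
#' @param seed seed for the effect-Z null resampling.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, library, track, tss, fpkm = NULL,
                            out_dir = "guidephase_out", doublings = NULL,
                            pseudocount = 1, threshold = 20,
                            null_pseudogenes = 10000L,
                            window = 50L, min_n = 10L,
                            filter_order = 4L, filter_cutoff = 0.03,
                            bin_width = 0.2,
                            expression_thresholds = c(2.7, 20),
                            range = c(-450L, 1450L),
                            missing_policy = "zero", seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline config from YAML
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Write a pipeline config to YAML
#' @param config a [pipeline_config()].
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(Filter(Negate(is.null), unclass(config)), path)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e)
    stop_data("pipeline stage '", name, "' failed: ", conditionMessage(e)))
}

#' Run the full scoring / occupancy / profile / association pipeline
#'
#' Executes phenotype scoring, hit calling and activity-score extraction;
#' per-guide target-site occupancy; TSS-relative windowed, smoothed activity
#' and occupancy profiles with peak/trough quantification; and the binned
#' rank-test plus linear-model association, writing each stage's tables and
#' a run manifest under `config$out_dir`. Any stage error aborts with the
#' stage name.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- stage("score", read_counts_tsv(config$counts))
  lib <- stage("score", read_library_tsv(config$library))
  dbl <- if (!is.null(config$doublings))
    stage("score", read_doublings_tsv(config$doublings)) else NULL

  nc_ids <- lib$sgrna_id[lib$is_negctrl]
  phen <- stage("score",
                compute_phenotypes(counts, nc_ids, config$pseudocount, dbl))
  stats_ <- stage("score",
                  gene_stats(phen, lib, config$null_pseudogenes, config$seed))
  hits <- stage("score", call_hits(stats_, config$threshold))
  act <- stage("score", activity_scores(phen, hits, lib))
  write_tsv(phen, file.path(config$out_dir, "phenotypes.tsv"))
  st_out <- merge(stats_, hits[, c("gene", "is_hit")], by = "gene")
  write_tsv(st_out, file.path(config$out_dir, "gene_stats.tsv"))
  write_tsv(act, file.path(config$out_dir, "activities.tsv"))

  track <- stage("occupancy", load_track(config$track))
  occ <- stage("occupancy",
               library_occupancy(track, lib, config$missing_policy))
  write_tsv(occ, file.path(config$out_dir, "occupancy.tsv"))

  tss <- stage("profile", read_tss_bed(config$tss))
  rel <- stage("profile", sgrna_rel_pos(lib, tss))
  act_rel <- merge(act, rel[, c("sgrna_id", "rel_pos")], by = "sgrna_id")
  prof <- stage("profile",
                windowed_profile(act_rel, config$window, config$min_n,
                                 config$range))
  prof <- stage("profile",
                smooth_profile(prof, config$filter_order, config$filter_cutoff))
  peaks <- stage("profile", find_peaks_troughs(prof))
  occ_prof <- stage("profile", tss_relative_signal(track, tss, config$range))
  write_tsv(prof, file.path(config$out_dir, "activity_profile.tsv"))
  write_tsv(occ_prof, file.path(config$out_dir, "occupancy_profile.tsv"))
  jsonlite::write_json(list(peaks = peaks$peaks, troughs = peaks$troughs,
                            amplitudes = peaks$amplitudes,
                            median_peak_spacing = peak_spacing(peaks)),
                       file.path(config$out_dir, "periodicity.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")

  assoc_df <- merge(merge(act, occ, by = "sgrna_id"),
                    lib[, c("sgrna_id", "protospacer_len", "seq_score")],
                    by = "sgrna_id")
  assoc_df$length <- assoc_df$protospacer_len + 3L  # protospacer + PAM
  bins <- stage("associate",
                bin_by_occupancy(assoc_df$activity, assoc_df$occupancy,
                                 config$bin_width))
  fits <- stage("associate", list(
    occupancy = fit_linear(assoc_df, "occupancy"),
    length = fit_linear(assoc_df, "length"),
    seq_score = fit_linear(assoc_df, "seq_score"),
    all = fit_linear(assoc_df, c("occupancy", "length", "seq_score"))))
  corrected <- stage("associate",
                     correct_activity(assoc_df$activity, assoc_df$seq_score,
                                      assoc_df$length))
  assoc_df$corrected <- as.numeric(corrected)
  fits$occupancy_corrected <- stage("associate",
    fit_linear(assoc_df, "occupancy", response = "corrected"))
  write_tsv(as.data.frame(bins), file.path(config$out_dir, "association.tsv"))
  jsonlite::write_json(
    lapply(fits, function(f) list(features = f$features,
                                  coefficients = as.list(f$coefficients),
                                  r2 = f$r2, n = f$n)),
    file.path(config$out_dir, "regression.json"),
    auto_unbox = TRUE, digits = NA)

  expr <- NULL
  if (!is.null(config$fpkm)) {
    fpkm <- stage("profile", read_fpkm_tsv(config$fpkm))
    expr <- stage("profile",
                  group_by_expression(fpkm, config$expression_thresholds))
    write_tsv(expr, file.path(config$out_dir, "expression_groups.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("guidephase")),
    parameters = Filter(Negate(is.null), unclass(config)),
    rows = list(counts = nrow(counts), library = nrow(lib),
                negctrl = sum(lib$is_negctrl),
                phenotypes = nrow(phen), genes_scored = nrow(stats_),
                hits = sum(hits$is_hit), activities = nrow(act),
                occupancy_sites = nrow(occ),
                association_rows = nrow(assoc_df)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(phenotypes = phen, gene_stats = stats_, hits = hits,
                 activities = act, occupancy = occ, profile = prof,
                 periodicity = peaks, occupancy_profile = occ_prof,
                 association = bins, fits = fits, expression = expr,
                 manifest = manifest))
}
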