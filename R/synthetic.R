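# Synthetic screens with ground truth: phased occupancy tracks, tiling
# sgRNA libraries, occupancy-suppressed true activities, negative-binomial
# counts, TSS records and FPKM tables, so every pipeline stage runs without
# external data.

#' Configuration for the synthetic screen generator
#'
#' Defaults emulate the statistical structure of a promoter-proximal CRISPRi
#' tiling screen in a human cell line: nucleosomes phased at a ~190 bp
#' repeat downstream (and mirrored upstream) of a nucleosome-depleted region
#' around the TSS, guide activity suppressed by target-site occupancy, and
#' sequencing counts with negative-binomial noise.
#'
#' @param n_genes number of targeted genes.
#' @param tiling_step spacing between consecutive guides (bp).
#' @param span_upstream,span_downstream tiled region around the TSS (bp).
#' @param repeat_length nucleosome repeat length (bp, default 190).
#' @param ndr_halfwidth half-width of the nucleosome-depleted region (bp).
#' @param first_dyad_offset position of the +1 nucleosome dyad (bp
#'   downstream of the TSS).
#' @param footprint_sigma Gaussian footprint s.d. per nucleosome (bp).
#' @param phasing_decay multiplicative decay of dyad height per nucleosome
#'   away from the TSS, in (0, 1].
#' @param occupancy_noise_sd per-base Gaussian noise s.d. (truncated at 0).
#' @param beta0,beta_occ,beta_q,beta_len true activity model coefficients:
#'   intercept, occupancy effect (< 0), sequence-score effect, and bonus for
#'   protospacer lengths 19-21.
#' @param activity_noise_sd s.d. of the activity noise term.
#' @param activity_max upper clip of the true activity.
#' @param fraction_hit fraction of genes with a real phenotype.
#' @param fraction_sensitizing fraction of hit genes whose knockdown
#'   sensitizes (negative phenotypes).
#' @param frac_negctrl negative controls as a fraction of targeting guides.
#' @param reads_per_sgrna mean sequencing depth per guide per sample.
#' @param nb_dispersion negative-binomial dispersion of counts.
#' @param replicates number of screen replicates.
#' @param doublings population-doubling difference between conditions.
#' @param protospacer_lengths,protospacer_weights sampling distribution of
#'   guide lengths.
#' @param fpkm_meanlog,fpkm_sdlog log-normal transcript FPKM parameters.
#' @param seed integer seed controlling all randomness.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 40L,
                             tiling_step = 5L,
                             span_upstream = 500L,
                             span_downstream = 1500L,
                             repeat_length = 190L,
                             ndr_halfwidth = 110L,
                             first_dyad_offset = 110L,
                             footprint_sigma = 40,
                             phasing_decay = 0.8,
                             occupancy_noise_sd = 0.05,
                             beta0 = 0.2,
                             beta_occ = -1.2,
                             beta_q = 0.9,
                             beta_len = 0.3,
                             activity_noise_sd = 0.15,
                             activity_max = 1.5,
                             fraction_hit = 0.8,
                             fraction_sensitizing = 0.5,
                             frac_negctrl = 0.05,
                             reads_per_sgrna = 500,
                             nb_dispersion = 0.01,
                             replicates = 2L,
                             doublings = 2,
                             protospacer_lengths = 18:25,
                             protospacer_weights = c(1, 4, 6, 4, 1, 1, 1, 1),
                             fpkm_meanlog = 2,
                             fpkm_sdlog = 1.2,
                             seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$repeat_length <= 2 * cfg$footprint_sigma)
    stop_data("repeat_length must exceed twice the footprint sigma")
  if (cfg$beta_occ >= 0) stop_data("beta_occ must be negative")
  if (cfg$n_genes < 1 || cfg$tiling_step < 1 ||
      cfg$span_upstream < 0 || cfg$span_downstream <= 0)
    stop_data("sizes must be positive")
  if (cfg$reads_per_sgrna <= 0) stop_data("read depth must be positive")
  if (cfg$span_downstream < cfg$first_dyad_offset)
    stop_data("span too small to hold one dyad")
  structure(cfg, class = "synthetic_config")
}

# gene layout on one synthetic chromosome, alternating strands
make_tss_table <- function(cfg) {
  spacing <- cfg$span_upstream + cfg$span_downstream + 4000L
  g <- seq_len(cfg$n_genes)
  gene <- sprintf("GENE%03d", g)
  data.frame(gene = gene, tss_id = paste0("p1@", gene), chrom = "chrS",
             strand = rep(c("+", "-"), length.out = cfg$n_genes),
             pos = 10000L + (g - 1L) * spacing, stringsAsFactors = FALSE)
}

# noise-free phased occupancy at TSS-relative positions d: a sum of Gaussian
# dyad footprints at first_dyad_offset + k*repeat_length downstream, with
# geometric height decay, mirrored upstream beyond the NDR
phased_occupancy <- function(d, cfg) {
  kmax <- ceiling(max(abs(d)) / cfg$repeat_length) + 1L
  centers <- cfg$first_dyad_offset + (0:kmax) * cfg$repeat_length
  w <- cfg$phasing_decay^(0:kmax)
  v <- numeric(length(d))
  for (i in seq_along(centers)) {
    v <- v + w[i] * exp(-(d - centers[i])^2 / (2 * cfg$footprint_sigma^2))
    v <- v + w[i] * exp(-(d + centers[i])^2 / (2 * cfg$footprint_sigma^2))
  }
  v
}

#' Generate a phased nucleosome occupancy track
#'
#' Per gene, the per-base signal is the noise-free phased profile (sum of
#' geometrically decaying Gaussian dyad footprints around the TSS, with a
#' nucleosome-depleted region over the TSS itself) plus Gaussian noise
#' truncated at zero.
#'
#' @param cfg a [synthetic_config()].
#' @param tss TSS table (defaults to the generator's own layout).
#' @return List with the [signal_track()] `track` and a data.frame `dyads`
#'   of ground-truth dyad centers (`gene`, `rel_pos`, `weight`).
#' @export
make_occupancy_track <- function(cfg, tss = make_tss_table(cfg)) {
  d <- seq(-cfg$span_upstream, cfg$span_downstream - 1L)
  base <- phased_occupancy(d, cfg)
  chroms <- list()
  vals_by_chrom <- list()
  for (i in seq_len(nrow(tss))) {
    noisy <- pmax(0, base + stats::rnorm(length(d), 0, cfg$occupancy_noise_sd))
    pos <- if (tss$strand[i] == "+") tss$pos[i] + d else tss$pos[i] - rev(d)
    vals_by_chrom[[i]] <- list(start = min(pos), values =
                                 if (tss$strand[i] == "+") noisy else rev(noisy))
  }
  starts <- vapply(vals_by_chrom, function(x) x$start, numeric(1))
  off <- min(starts)
  len <- max(vapply(vals_by_chrom, function(x) x$start + length(x$values),
                    numeric(1))) - off
  v <- rep(NA_real_, len)
  for (x in vals_by_chrom)
    v[(x$start - off + 1):(x$start - off + length(x$values))] <- x$values

  kmax <- ceiling(max(cfg$span_upstream, cfg$span_downstream) /
                    cfg$repeat_length)
  centers <- cfg$first_dyad_offset + (0:kmax) * cfg$repeat_length
  dyads <- do.call(rbind, lapply(tss$gene, function(g)
    data.frame(gene = g,
               rel_pos = c(-rev(centers), centers),
               weight = c(rev(cfg$phasing_decay^(0:kmax)),
                          cfg$phasing_decay^(0:kmax)))))
  dyads <- dyads[abs(dyads$rel_pos) <= max(cfg$span_upstream,
                                           cfg$span_downstream), ]
  list(track = signal_track(list(chrS = list(offset = off, values = v)),
                            provenance = "synthetic phased occupancy"),
       dyads = dyads)
}

#' Generate a tiling sgRNA library
#'
#' Guides are placed every `tiling_step` bp across the span around each TSS
#' on alternating strands, with protospacer lengths sampled from the
#' configured multiset, Beta(2, 2) sequence scores, and a configurable
#' fraction of non-targeting negative controls.
#'
#' @param cfg a [synthetic_config()].
#' @param tss TSS table (defaults to the generator's own layout).
#' @return Library data.frame: `sgrna_id`, `gene`, `tss_id`, `chrom`,
#'   `strand` (targeted gene), `sgrna_strand`, `pam_g3_pos`,
#'   `protospacer_len`, `target_start`, `target_end`, `seq_score`,
#'   `is_negctrl`.
#' @export
make_library <- function(cfg, tss = make_tss_table(cfg)) {
  rel <- seq(-cfg$span_upstream, cfg$span_downstream - 1L, by = cfg$tiling_step)
  if (length(rel) == 0) stop_data("span/step yields zero guides")
  rows <- lapply(seq_len(nrow(tss)), function(i) {
    n <- length(rel)
    pam <- if (tss$strand[i] == "+") tss$pos[i] + rel else tss$pos[i] - rel
    L <- sample(cfg$protospacer_lengths, n, replace = TRUE,
                prob = cfg$protospacer_weights)
    sg_strand <- rep(c("+", "-"), length.out = n)
    start <- ifelse(sg_strand == "+", pam - (L + 2L), pam)
    data.frame(sgrna_id = sprintf("%s_sg%04d", tss$gene[i], seq_len(n)),
               gene = tss$gene[i], tss_id = tss$tss_id[i],
               chrom = tss$chrom[i], strand = tss$strand[i],
               sgrna_strand = sg_strand, pam_g3_pos = as.integer(pam),
               protospacer_len = as.integer(L),
               target_start = as.integer(start),
               target_end = as.integer(start + L + 3L),
               seq_score = stats::rbeta(n, 2, 2),
               is_negctrl = FALSE, stringsAsFactors = FALSE)
  })
  lib <- do.call(rbind, rows)
  n_nc <- max(2L, round(cfg$frac_negctrl * nrow(lib)))
  nc <- data.frame(sgrna_id = sprintf("NC_%04d", seq_len(n_nc)),
                   gene = NA_character_, tss_id = NA_character_,
                   chrom = NA_character_, strand = NA_character_,
                   sgrna_strand = NA_character_, pam_g3_pos = NA_integer_,
                   protospacer_len = as.integer(
                     sample(cfg$protospacer_lengths, n_nc, replace = TRUE,
                            prob = cfg$protospacer_weights)),
                   target_start = NA_integer_, target_end = NA_integer_,
                   seq_score = stats::rbeta(n_nc, 2, 2),
                   is_negctrl = TRUE, stringsAsFactors = FALSE)
  rbind(lib, nc)
}

#' True per-sgRNA activity under the generating model
#'
#' Activity decreases linearly in target-site occupancy (the generating
#' encoding of nucleosome exclusion), increases with the sequence score and
#' with a modal protospacer length (19-21 bp), plus Gaussian noise, clipped
#' to `[0, activity_max]`. Negative controls get activity 0.
#'
#' @param cfg a [synthetic_config()].
#' @param occupancy,seq_score,length aligned per-sgRNA vectors.
#' @param is_negctrl logical vector.
#' @return Numeric vector of true activities.
#' @export
true_activity <- function(cfg, occupancy, seq_score, length,
                          is_negctrl = rep(FALSE, base::length(occupancy))) {
  eps <- stats::rnorm(base::length(occupancy), 0, cfg$activity_noise_sd)
  a <- clip(cfg$beta0 + cfg$beta_occ * occupancy + cfg$beta_q * seq_score +
              cfg$beta_len * (length %in% 19:21) + eps, 0, cfg$activity_max)
  a[is_negctrl] <- 0
  a
}

#' Simulate screen counts from phenotypes
#'
#' Initial abundances are log-normal; expected final abundance multiplies
#' the initial by `2^(phenotype * doublings)`; counts for both conditions
#' are drawn negative-binomially at the configured depth and dispersion,
#' independently per replicate.
#'
#' @param cfg a [synthetic_config()].
#' @param phenotypes data.frame with `sgrna_id` and `phenotype` (log2 units
#'   per doubling).
#' @param screen_id screen identifier for the output table.
#' @return List with `counts` (sgrna_id, screen_id, replicate, count_a,
#'   count_b) and `doublings` (screen_id, replicate, doublings).
#' @export
simulate_counts <- function(cfg, phenotypes, screen_id = "screen1") {
  if (!all(is.finite(phenotypes$phenotype)))
    stop_data("phenotypes must be finite")
  n <- nrow(phenotypes)
  depth <- cfg$reads_per_sgrna * n
  size <- 1 / cfg$nb_dispersion
  reps <- lapply(seq_len(cfg$replicates), function(r) {
    w0 <- stats::rlnorm(n, 0, 0.5)
    w0 <- w0 / sum(w0)
    wf <- w0 * 2^(phenotypes$phenotype * cfg$doublings)
    wf <- wf / sum(wf)
    data.frame(sgrna_id = phenotypes$sgrna_id, screen_id = screen_id,
               replicate = r,
               count_a = stats::rnbinom(n, mu = w0 * depth, size = size),
               count_b = stats::rnbinom(n, mu = wf * depth, size = size),
               stringsAsFactors = FALSE)
  })
  list(counts = do.call(rbind, reps),
       doublings = data.frame(screen_id = screen_id,
                              replicate = seq_len(cfg$replicates),
                              doublings = cfg$doublings))
}

#' Generate a complete synthetic screen bundle with ground truth
#'
#' Produces, under a single seed, all five pipeline inputs (counts, library,
#' occupancy track, TSS records, FPKM table) together with the ground truth
#' needed to score recovery at any stage. When `dir` is given, the inputs
#' are written in the pipeline's own file formats plus a truth sidecar JSON.
#'
#' @param cfg a [synthetic_config()].
#' @param dir optional output directory (created if needed).
#' @return List of class `synthetic_truth`: `cfg`, `tss`, `track`, `dyads`,
#'   `library`, `truth` (per-sgRNA true occupancy/activity/phenotype and
#'   per-gene hit status, strength and sign), `counts`, `doublings`, `fpkm`,
#'   and `paths` (when written).
#' @export
generate_screen_data <- function(cfg = synthetic_config(), dir = NULL) {
  set.seed(cfg$seed)
  tss <- make_tss_table(cfg)
  occ <- make_occupancy_track(cfg, tss)
  lib <- make_library(cfg, tss)

  # noise-free occupancy truth: mean of the phased curve over each target site
  targ <- !lib$is_negctrl
  o_true <- numeric(nrow(lib))
  if (any(targ)) {
    m <- match(lib$tss_id[targ], tss$tss_id)
    sgn <- ifelse(tss$strand[m] == "+", 1L, -1L)
    o_true[targ] <- vapply(which(targ), function(i) {
      j <- match(lib$tss_id[i], tss$tss_id)
      rel <- (lib$target_start[i]:(lib$target_end[i] - 1L) - tss$pos[j]) *
        (if (tss$strand[j] == "+") 1L else -1L)
      mean(phased_occupancy(rel, cfg))
    }, numeric(1))
  }
  a_true <- true_activity(cfg, o_true, lib$seq_score, lib$protospacer_len,
                          lib$is_negctrl)

  genes <- tss$gene
  is_hit <- stats::runif(length(genes)) < cfg$fraction_hit
  sign <- ifelse(stats::runif(length(genes)) < cfg$fraction_sensitizing, -1, 1)
  strength <- stats::runif(length(genes), 1, 1.6)
  gi <- match(lib$gene, genes)
  mult <- ifelse(is.na(gi), 0,
                 sign[gi] * strength[gi] * ifelse(is_hit[gi], 1, 0.05))
  phen_true <- mult * a_true

  sim <- simulate_counts(cfg, data.frame(sgrna_id = lib$sgrna_id,
                                         phenotype = phen_true))

  fpkm <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene = g,
               transcript_id = paste0(g, ".t", 1:2),
               fpkm = stats::rlnorm(2, cfg$fpkm_meanlog, cfg$fpkm_sdlog),
               stringsAsFactors = FALSE)))

  truth <- data.frame(sgrna_id = lib$sgrna_id, gene = lib$gene,
                      occupancy_true = o_true, activity_true = a_true,
                      phenotype_true = phen_true, stringsAsFactors = FALSE)
  gene_truth <- data.frame(gene = genes, is_hit = is_hit, sign = sign,
                           strength = strength, stringsAsFactors = FALSE)

  out <- structure(list(cfg = cfg, tss = tss, track = occ$track,
                        dyads = occ$dyads, library = lib, truth = truth,
                        gene_truth = gene_truth, counts = sim$counts,
                        doublings = sim$doublings, fpkm = fpkm,
                        paths = NULL),
                   class = "synthetic_truth")
  if (!is.null(dir)) out$paths <- write_screen_bundle(out, dir)
  out
}

write_screen_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(counts = file.path(dir, "counts.tsv"),
                doublings = file.path(dir, "doublings.tsv"),
                library = file.path(dir, "library.tsv"),
                track = file.path(dir, "track.bedGraph"),
                tss = file.path(dir, "tss.bed"),
                fpkm = file.path(dir, "fpkm.tsv"),
                truth = file.path(dir, "truth.json"))
  write_tsv(bundle$counts, paths$counts)
  write_tsv(bundle$doublings, paths$doublings)
  write_tsv(bundle$library, paths$library)
  write_bedgraph(bundle$track, paths$track)
  gr <- GenomicRanges::GRanges(bundle$tss$chrom,
                               IRanges::IRanges(bundle$tss$pos + 1L,
                                                bundle$tss$pos + 1L),
                               strand = bundle$tss$strand)
  S4Vectors::mcols(gr)$name <- bundle$tss$tss_id
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, paths$tss, format = "BED")
  write_tsv(bundle$fpkm, paths$fpkm)
  jsonlite::write_json(list(config = unclass(bundle$cfg),
                            gene_truth = bundle$gene_truth,
                            sgrna_truth = bundle$truth,
                            dyads = bundle$dyads),
                       paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  paths
}
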