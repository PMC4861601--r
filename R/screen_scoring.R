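# Screen scoring: raw sgRNA counts -> phenotypes -> gene stats -> hits ->
# activity scores and phenotype-signed Z scores.

#' Compute sgRNA phenotypes from screen count tables
#'
#' A phenotype is the log2 enrichment of reads-per-million between two screen
#' conditions (e.g. untreated vs treated, or initial vs final timepoint),
#' centered on the negative-control median within each replicate, optionally
#' divided by the difference in population doublings, and averaged across
#' replicates. A pseudocount is added to both RPM values so zero counts are
#' finite.
#'
#' @param counts data.frame with columns `sgrna_id`, `screen_id`, `replicate`,
#'   `count_a` (reference condition), `count_b` (selected condition).
#' @param negctrl_ids character vector of negative-control sgRNA ids; their
#'   per-replicate median phenotype defines zero.
#' @param pseudocount positive value added to each RPM before the log ratio
#'   (default 1).
#' @param doublings optional data.frame with columns `screen_id`, `replicate`,
#'   `doublings` (> 0). When supplied, each replicate's phenotypes are divided
#'   by its doubling difference so phenotypes are in log2 units per doubling.
#' @return data.frame with columns `sgrna_id`, `screen_id`, `phenotype`
#'   (replicate-averaged). The per-replicate phenotypes are attached as
#'   attribute `"replicates"`.
#' @export
compute_phenotypes <- function(counts, negctrl_ids, pseudocount = 1,
                               doublings = NULL) {
  check_cols(counts, c("sgrna_id", "screen_id", "replicate", "count_a", "count_b"),
             "counts table")
  if (pseudocount <= 0) stop_data("pseudocount must be > 0")
  if (any(counts$count_a < 0) || any(counts$count_b < 0))
    stop_data("counts must be nonnegative")
  if (length(negctrl_ids) == 0)
    stop_data("no negative controls supplied; centering is undefined")
  if (!is.null(doublings))
    check_cols(doublings, c("screen_id", "replicate", "doublings"), "doublings table")

  key <- interaction(counts$screen_id, counts$replicate, drop = TRUE)
  pieces <- lapply(split(counts, key), function(rep_df) {
    scr <- rep_df$screen_id[1]
    repl <- rep_df$replicate[1]
    if (anyDuplicated(rep_df$sgrna_id))
      stop_data("duplicated sgrna_id within screen ", scr, " replicate ", repl)
    tot_a <- sum(rep_df$count_a)
    tot_b <- sum(rep_df$count_b)
    if (tot_a == 0 || tot_b == 0)
      stop_data("zero total reads in a condition of screen ", scr,
                " replicate ", repl)
    rpm_a <- rep_df$count_a / tot_a * 1e6
    rpm_b <- rep_df$count_b / tot_b * 1e6
    p <- log2((rpm_b + pseudocount) / (rpm_a + pseudocount))
    nc <- p[rep_df$sgrna_id %in% negctrl_ids]
    if (length(nc) == 0)
      stop_data("no negative-control sgRNAs found in screen ", scr,
                " replicate ", repl)
    p <- p - stats::median(nc)
    if (!is.null(doublings)) {
      hit <- doublings$screen_id == scr & doublings$replicate == repl
      if (sum(hit) != 1)
        stop_data("doublings missing (or duplicated) for screen ", scr,
                  " replicate ", repl)
      d <- doublings$doublings[hit]
      if (!is.finite(d) || d <= 0)
        stop_data("doublings must be finite and > 0")
      p <- p / d
    }
    data.frame(sgrna_id = rep_df$sgrna_id, screen_id = scr,
               replicate = repl, phenotype = p, stringsAsFactors = FALSE)
  })
  per_rep <- do.call(rbind, pieces)
  rownames(per_rep) <- NULL

  # every sgRNA must appear in every replicate of its screen
  for (scr in unique(per_rep$screen_id)) {
    sub <- per_rep[per_rep$screen_id == scr, ]
    tab <- table(sub$sgrna_id)
    n_rep <- length(unique(sub$replicate))
    if (any(tab != n_rep))
      stop_data("sgRNA(s) missing from a replicate of screen ", scr, ": ",
                paste(utils::head(names(tab)[tab != n_rep], 5), collapse = ", "))
  }

  agg <- stats::aggregate(phenotype ~ sgrna_id + screen_id, data = per_rep, FUN = mean)
  agg <- agg[order(agg$screen_id, agg$sgrna_id), ]
  rownames(agg) <- NULL
  attr(agg, "replicates") <- per_rep
  agg
}

#' Composite hit score from an effect Z score and a Mann-Whitney p-value
#'
#' @param z effect Z score (effect size standardized against a
#'   negative-control null).
#' @param p two-tailed Mann-Whitney p-value in (0, 1].
#' @return `|z * log10(p)|`, a nonnegative score integrating effect size and
#'   statistical confidence.
#' @export
hit_score <- function(z, p) abs(z * log10(p))

#' Per-gene effect sizes, Mann-Whitney p-values and hit scores
#'
#' For each (gene, TSS, screen), the effect size is the signed mean of the 3
#' sgRNA phenotypes largest in absolute value; the confidence value is a
#' two-tailed Mann-Whitney p of the gene's sgRNAs against all negative
#' controls. The effect Z score standardizes the effect against a null of
#' size-matched pseudo-genes resampled from the negative-control phenotypes,
#' and the composite hit score is `|z * log10(p)|`.
#'
#' @param phen phenotype table from [compute_phenotypes()].
#' @param library sgRNA library data.frame with at least `sgrna_id`, `gene`,
#'   `tss_id`, `is_negctrl`.
#' @param null_pseudogenes number of negative-control pseudo-genes used to
#'   build the effect-size null (default 10000).
#' @param seed integer seed for the pseudo-gene resampling.
#' @return data.frame with one row per (gene, tss_id, screen_id): `n_sgrnas`,
#'   `effect`, `mw_p`, `z`, `score`.
#' @export
gene_stats <- function(phen, library, null_pseudogenes = 10000L, seed = 1L) {
  check_cols(phen, c("sgrna_id", "screen_id", "phenotype"), "phenotype table")
  check_cols(library, c("sgrna_id", "gene", "tss_id", "is_negctrl"), "library")
  nc_ids <- library$sgrna_id[library$is_negctrl]
  if (length(nc_ids) == 0) stop_data("library contains no negative controls")

  lib_t <- library[!library$is_negctrl, c("sgrna_id", "gene", "tss_id")]
  df <- merge(phen, lib_t, by = "sgrna_id")

  set.seed(seed)
  out <- list()
  for (scr in sort(unique(phen$screen_id))) {
    p_scr <- phen[phen$screen_id == scr, ]
    nc <- p_scr$phenotype[p_scr$sgrna_id %in% nc_ids]
    if (length(nc) == 0)
      stop_data("no negative-control phenotypes in screen ", scr)
    d_scr <- df[df$screen_id == scr, ]
    d_scr <- d_scr[order(d_scr$gene, d_scr$tss_id, d_scr$sgrna_id), ]
    grp <- split(d_scr$phenotype,
                 paste(d_scr$gene, d_scr$tss_id, sep = "\t"))
    sizes <- vapply(grp, length, integer(1))
    if (any(sizes < 3))
      stop_data("gene/TSS with fewer than 3 sgRNAs in screen ", scr, ": ",
                paste(utils::head(names(sizes)[sizes < 3], 5), collapse = ", "))

    # one null per distinct gene size: effect sizes of size-matched
    # pseudo-genes resampled (with replacement) from the negative controls
    null_mu <- null_sd <- numeric(0)
    for (n in sort(unique(sizes))) {
      idx <- matrix(sample.int(length(nc), n * null_pseudogenes, replace = TRUE),
                    nrow = n)
      eff <- apply(idx, 2, function(j) strongest_mean(nc[j]))
      s <- stats::sd(eff)
      if (s == 0) stop_data("degenerate null (sd = 0) for gene size ", n)
      null_mu[as.character(n)] <- mean(eff)
      null_sd[as.character(n)] <- s
    }

    keys <- strsplit(names(grp), "\t", fixed = TRUE)
    rows <- lapply(seq_along(grp), function(i) {
      ph <- grp[[i]]
      e <- strongest_mean(ph)
      p <- mann_whitney_two_tailed(ph, nc)
      z <- (e - null_mu[as.character(length(ph))]) /
        null_sd[as.character(length(ph))]
      data.frame(gene = keys[[i]][1], tss_id = keys[[i]][2], screen_id = scr,
                 n_sgrnas = length(ph), effect = e, mw_p = p, z = unname(z),
                 score = unname(hit_score(z, p)), stringsAsFactors = FALSE)
    })
    out[[scr]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call hit genes from per-(gene, TSS, screen) statistics
#'
#' A gene is a hit if its maximal score over all its TSSs and screens reaches
#' the threshold (inclusive). The argmax (tss, screen) is recorded so activity
#' scores can later be extracted from the screen in which the gene scored;
#' ties are broken by lexicographic screen id, then TSS id.
#'
#' @param stats output of [gene_stats()], possibly over several screens.
#' @param threshold minimum hit score (default 20, inclusive).
#' @return data.frame with one row per gene: best `tss_id`, `screen_id`,
#'   `score`, and logical `is_hit`.
#' @export
call_hits <- function(stats, threshold = 20) {
  check_cols(stats, c("gene", "tss_id", "screen_id", "score"), "gene stats")
  if (nrow(stats) == 0) stop_data("empty gene stats")
  ord <- order(stats$gene, -stats$score, stats$screen_id, stats$tss_id)
  st <- stats[ord, ]
  best <- st[!duplicated(st$gene), c("gene", "tss_id", "screen_id", "score")]
  best$is_hit <- best$score >= threshold
  rownames(best) <- NULL
  best
}

#' Per-sgRNA activity scores for hit genes
#'
#' For each hit gene, phenotypes are taken from the (tss, screen) in which the
#' gene scored as a hit, and divided by the signed mean of the 3 phenotypes
#' largest in absolute value. The resulting activity scores are distributed
#' around 0 for inactive sgRNAs and around 1 for highly active ones, in both
#' protective and sensitizing screens.
#'
#' @param phen phenotype table from [compute_phenotypes()].
#' @param hits output of [call_hits()]; only rows with `is_hit` are used.
#' @param library sgRNA library data.frame (`sgrna_id`, `gene`, `tss_id`,
#'   `is_negctrl`).
#' @return data.frame with columns `sgrna_id`, `gene`, `tss_id`, `activity`,
#'   `source_screen`.
#' @export
activity_scores <- function(phen, hits, library) {
  check_cols(hits, c("gene", "tss_id", "screen_id", "is_hit"), "hits")
  hits <- hits[hits$is_hit, ]
  lib_t <- library[!library$is_negctrl, ]
  out <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    sg <- lib_t$sgrna_id[lib_t$gene == h$gene & lib_t$tss_id == h$tss_id]
    ph <- phen[phen$screen_id == h$screen_id & phen$sgrna_id %in% sg, ]
    if (nrow(ph) < 3)
      stop_data("hit gene ", h$gene, " has fewer than 3 phenotypes in screen ",
                h$screen_id)
    m <- strongest_mean(ph$phenotype)
    if (m == 0)
      stop_data("activity normalizer is 0 for gene ", h$gene)
    data.frame(sgrna_id = ph$sgrna_id, gene = h$gene, tss_id = h$tss_id,
               activity = ph$phenotype / m, source_screen = h$screen_id,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) stop_data("no hit genes")
  rownames(res) <- NULL
  res
}

#' Phenotype-signed Z scores for a tiling screen
#'
#' Phenotypes are divided by the standard deviation of the negative-control
#' phenotypes and multiplied by -1 for genes whose knockdown is sensitizing,
#' so positive values always represent the expected knockdown phenotype.
#'
#' @param phen phenotype table restricted to one screen (or pass `screen`).
#' @param library sgRNA library data.frame (`sgrna_id`, `gene`, `is_negctrl`).
#' @param expected_signs named numeric vector, gene -> +1 (protective) or -1
#'   (sensitizing).
#' @param screen optional screen id to select from `phen`.
#' @return data.frame with columns `sgrna_id`, `gene`, `z_signed`,
#'   `expected_sign` for all targeting sgRNAs.
#' @export
ricin_z_scores <- function(phen, library, expected_signs, screen = NULL) {
  check_cols(phen, c("sgrna_id", "screen_id", "phenotype"), "phenotype table")
  if (!is.null(screen)) phen <- phen[phen$screen_id == screen, ]
  if (length(unique(phen$screen_id)) != 1)
    stop_data("phenotypes span several screens; pass `screen`")
  nc_ids <- library$sgrna_id[library$is_negctrl]
  nc <- phen$phenotype[phen$sgrna_id %in% nc_ids]
  if (length(nc) < 2) stop_data("need at least 2 negative-control phenotypes")
  sigma <- stats::sd(nc)
  if (sigma == 0) stop_data("negative-control phenotypes have zero variance")
  lib_t <- library[!library$is_negctrl, c("sgrna_id", "gene")]
  df <- merge(phen, lib_t, by = "sgrna_id")
  s <- expected_signs[df$gene]
  if (any(is.na(s)))
    stop_data("missing expected sign for gene(s): ",
              paste(utils::head(unique(df$gene[is.na(s)]), 5), collapse = ", "))
  if (!all(s %in% c(-1, 1))) stop_data("expected signs must be +1 or -1")
  out <- data.frame(sgrna_id = df$sgrna_id, gene = df$gene,
                    z_signed = unname(s) * df$phenotype / sigma,
                    expected_sign = unname(s), stringsAsFactors = FALSE)
  out[order(out$sgrna_id), , drop = FALSE]
}
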