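# Small, fast synthetic configurations used across test files.

small_cfg <- function(seed = 1L, ...) {
  synthetic_config(n_genes = 8L, tiling_step = 20L, span_upstream = 400L,
                   span_downstream = 1000L, seed = seed, ...)
}

# counts table for hand-built screens: one replicate unless reps given
counts_df <- function(ids, a, b, screen = "s1", replicate = 1L) {
  data.frame(sgrna_id = ids, screen_id = screen, replicate = replicate,
             count_a = a, count_b = b, stringsAsFactors = FALSE)
}

# minimal library for scoring tests: genes each with `per_gene` guides plus
# negative controls; no genomic placement needed
scoring_library <- function(genes, per_gene = 5L, n_nc = 10L) {
  tg <- do.call(rbind, lapply(genes, function(g)
    data.frame(sgrna_id = sprintf("%s_%02d", g, seq_len(per_gene)),
               gene = g, tss_id = paste0("p1@", g), is_negctrl = FALSE,
               stringsAsFactors = FALSE)))
  nc <- data.frame(sgrna_id = sprintf("nc_%02d", seq_len(n_nc)),
                   gene = NA_character_, tss_id = NA_character_,
                   is_negctrl = TRUE, stringsAsFactors = FALSE)
  rbind(tg, nc)
}

phen_df <- function(ids, p, screen = "s1") {
  data.frame(sgrna_id = ids, screen_id = screen, phenotype = p,
             stringsAsFactors = FALSE)
}
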