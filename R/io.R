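# Tab-separated readers/writers for the pipeline's tables.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv <- function(path, what) {
  if (!file.exists(path)) stop_data(what, " file not found: ", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Read an sgRNA counts table
#'
#' Expects columns `sgrna_id`, `screen_id`, `replicate`, `count_a`,
#' `count_b` (tab-separated).
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_counts_tsv <- function(path) {
  check_cols(read_tsv(path, "counts"),
             c("sgrna_id", "screen_id", "replicate", "count_a", "count_b"),
             "counts TSV")
}

#' Read a per-replicate doublings sidecar table
#'
#' @param path TSV with columns `screen_id`, `replicate`, `doublings`.
#' @return data.frame.
#' @export
read_doublings_tsv <- function(path) {
  check_cols(read_tsv(path, "doublings"),
             c("screen_id", "replicate", "doublings"), "doublings TSV")
}

#' Read an sgRNA library annotation table
#'
#' One row per guide; coordinates are 0-based half-open. Validates the
#' target-interval invariants for targeting guides: interval length equals
#' protospacer length + 3 (PAM), and the PAM 3' G lies inside the interval.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_library_tsv <- function(path) {
  lib <- check_cols(read_tsv(path, "library"),
                    c("sgrna_id", "gene", "tss_id", "chrom", "strand",
                      "pam_g3_pos", "protospacer_len", "target_start",
                      "target_end", "seq_score", "is_negctrl"), "library TSV")
  lib$is_negctrl <- as.logical(lib$is_negctrl)
  t <- lib[!lib$is_negctrl, ]
  if (any(t$target_end - t$target_start != t$protospacer_len + 3L))
    stop_data("library: target interval length must equal protospacer_len + 3")
  if (any(t$pam_g3_pos < t$target_start | t$pam_g3_pos >= t$target_end))
    stop_data("library: pam_g3_pos must lie inside the target interval")
  lib
}

#' Read a transcript FPKM table
#'
#' @param path TSV with columns `gene`, `transcript_id`, `fpkm`.
#' @return data.frame.
#' @export
read_fpkm_tsv <- function(path) {
  check_cols(read_tsv(path, "FPKM"), c("gene", "fpkm"), "FPKM TSV")
}
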