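# Per-base occupancy signal: dense per-chromosome track container, readers,
# target-site means and TSS-relative aggregation.
#
# All internal coordinates are 0-based half-open; bedGraph is native 0-based,
# 1-based formats (wiggle, GRanges) are converted at the boundary.

#' Construct a per-base signal track
#'
#' A signal track holds, per chromosome, a 0-based offset and a dense numeric
#' vector of per-base values. Positions outside the stored span, or stored as
#' `NA`, are "missing" (e.g. bases with no MNase-seq coverage).
#'
#' @param chroms named list; each element is `list(offset = <0-based int>,
#'   values = <numeric vector>)`.
#' @param provenance free-text description of where the signal came from.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(chroms = list(), provenance = "") {
  for (ch in chroms) {
    stopifnot(is.numeric(ch$offset), is.numeric(ch$values))
    if (any(ch$values < 0, na.rm = TRUE))
      stop_data("signal values must be nonnegative")
  }
  structure(list(chroms = chroms, provenance = provenance),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track:", length(x$chroms), "chromosome(s)\n")
  for (nm in names(x$chroms)) {
    ch <- x$chroms[[nm]]
    cat("  ", nm, ": [", ch$offset, ", ", ch$offset + length(ch$values),
        ") ", sum(!is.na(ch$values)), " covered bases\n", sep = "")
  }
  invisible(x)
}

granges_to_track <- function(gr, provenance = "") {
  if (any(S4Vectors::mcols(gr)$score < 0))
    stop_data("track contains negative values")
  if (S4Vectors::isSorted(gr) == FALSE) {
    warning("track intervals were not sorted; sorting")
    gr <- GenomicRanges::sort(gr)
  }
  red <- GenomicRanges::reduce(gr)
  if (sum(GenomicRanges::width(red)) < sum(GenomicRanges::width(gr)))
    stop_data("track contains overlapping intervals")
  chroms <- list()
  for (chr in as.character(unique(GenomicRanges::seqnames(gr)))) {
    sub <- gr[GenomicRanges::seqnames(gr) == chr]
    off <- min(GenomicRanges::start(sub)) - 1L          # 0-based
    len <- max(GenomicRanges::end(sub)) - off
    v <- rep(NA_real_, len)
    st <- GenomicRanges::start(sub) - 1L - off + 1L     # index into v
    en <- GenomicRanges::end(sub) - off
    sc <- S4Vectors::mcols(sub)$score
    for (i in seq_along(sub)) v[st[i]:en[i]] <- sc[i]
    chroms[[chr]] <- list(offset = off, values = v)
  }
  signal_track(chroms, provenance)
}

#' Load a per-base signal track from bedGraph or wiggle
#'
#' Interval records are expanded to per-base values. bedGraph coordinates are
#' 0-based half-open; fixedStep/variableStep wiggle is read with its native
#' 1-based semantics. Overlapping intervals or negative values are errors;
#' unsorted input is sorted with a warning; an empty file yields an empty
#' track whose lookups are all missing.
#'
#' @param path file path.
#' @param format `"bedgraph"` or `"wiggle"`.
#' @return A [signal_track()].
#' @export
load_track <- function(path, format = c("bedgraph", "wiggle")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_data("track file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(body) == 0)
    return(signal_track(provenance = path))
  gr <- rtracklayer::import(path,
                            format = if (format == "bedgraph") "bedGraph" else "wig")
  granges_to_track(gr, provenance = path)
}

#' Per-base values at 0-based positions
#'
#' @param track a [signal_track()].
#' @param chrom chromosome name.
#' @param pos integer vector of 0-based positions.
#' @return Numeric vector; `NA` for positions outside coverage or on a
#'   chromosome absent from the track.
#' @export
track_values <- function(track, chrom, pos) {
  ch <- track$chroms[[chrom]]
  if (is.null(ch)) return(rep(NA_real_, length(pos)))
  idx <- pos - ch$offset + 1
  idx[idx < 1 | idx > length(ch$values)] <- NA_integer_
  ch$values[idx]
}

#' Mean occupancy over an sgRNA target site
#'
#' The target-site occupancy is the arithmetic mean of the per-base signal
#' over the interval spanning the 5' end of the protospacer through the 3'
#' end of the PAM. Under `missing_policy = "zero"` (ENCODE-style sparse
#' coverage treated as no protection) uncovered bases contribute 0; under
#' `"skip"` they are excluded from the mean. A site on a chromosome absent
#' from the track yields `NA`.
#'
#' @param track a [signal_track()].
#' @param chrom chromosome.
#' @param start,end 0-based half-open target interval.
#' @param missing_policy `"zero"` or `"skip"`.
#' @return Mean signal (scalar), with attribute `n_missing` giving the number
#'   of uncovered bases in the interval.
#' @export
site_occupancy <- function(track, chrom, start, end,
                           missing_policy = c("zero", "skip")) {
  missing_policy <- match.arg(missing_policy)
  if (end <= start) stop_data("target interval is empty")
  if (is.null(track$chroms[[chrom]]))
    return(structure(NA_real_, n_missing = end - start))
  v <- track_values(track, chrom, start:(end - 1))
  n_miss <- sum(is.na(v))
  val <- if (missing_policy == "zero") {
    v[is.na(v)] <- 0
    mean(v)
  } else {
    if (n_miss == length(v)) NA_real_ else mean(v, na.rm = TRUE)
  }
  structure(val, n_missing = n_miss)
}

#' Target-site occupancy for every sgRNA in a library
#'
#' @param track a [signal_track()].
#' @param library sgRNA library data.frame with `sgrna_id`, `chrom`,
#'   `target_start`, `target_end`, `is_negctrl`. Negative controls (no
#'   genomic site) are skipped.
#' @param missing_policy see [site_occupancy()].
#' @return data.frame `sgrna_id`, `occupancy`, `n_missing`.
#' @export
library_occupancy <- function(track, library,
                              missing_policy = c("zero", "skip")) {
  missing_policy <- match.arg(missing_policy)
  check_cols(library, c("sgrna_id", "chrom", "target_start", "target_end"),
             "library")
  lib <- library[!(library$is_negctrl %||% FALSE), ]
  occ <- numeric(nrow(lib))
  nm <- integer(nrow(lib))
  for (i in seq_len(nrow(lib))) {
    o <- site_occupancy(track, lib$chrom[i], lib$target_start[i],
                        lib$target_end[i], missing_policy)
    occ[i] <- as.numeric(o)
    nm[i] <- attr(o, "n_missing")
  }
  data.frame(sgrna_id = lib$sgrna_id, occupancy = occ, n_missing = nm,
             stringsAsFactors = FALSE)
}

#' TSS-relative mean signal across genes
#'
#' For each relative position d (downstream of the TSS positive, in gene
#' orientation), the mean of the track value at `pos + d` for + strand genes
#' and `pos - d` for - strand genes, across all genes with coverage there.
#'
#' @param track a [signal_track()].
#' @param tss data.frame with `gene`, `chrom`, `strand` (`"+"`/`"-"`),
#'   `pos` (0-based TSS coordinate).
#' @param range_bp integer length-2, relative positions `range_bp[1]:range_bp[2]`.
#' @return data.frame `rel_pos`, `value` (NA where no gene contributes),
#'   `n_genes` (count of contributing genes per position).
#' @export
tss_relative_signal <- function(track, tss, range_bp = c(-500L, 1500L)) {
  check_cols(tss, c("gene", "chrom", "strand", "pos"), "TSS table")
  if (nrow(tss) == 0) stop_data("empty TSS list")
  d <- seq(range_bp[1], range_bp[2])
  acc <- matrix(NA_real_, nrow = nrow(tss), ncol = length(d))
  for (i in seq_len(nrow(tss))) {
    pos <- if (tss$strand[i] == "+") tss$pos[i] + d else tss$pos[i] - d
    acc[i, ] <- track_values(track, tss$chrom[i], pos)
  }
  n <- colSums(!is.na(acc))
  val <- colMeans(acc, na.rm = TRUE)
  val[n == 0] <- NA_real_
  data.frame(rel_pos = d, value = val, n_genes = n)
}

#' Write a signal track as bedGraph
#'
#' Runs of equal values are merged into 0-based half-open interval records;
#' missing (NA) stretches are omitted. Values are printed at full precision
#' so a write/load round trip is exact.
#'
#' @param track a [signal_track()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(track$chroms)) {
    ch <- track$chroms[[chr]]
    v <- ch$values
    n <- length(v)
    if (n == 0) next
    same <- is.na(v[-1]) & is.na(v[-n]) |
      (!is.na(v[-1]) & !is.na(v[-n]) & v[-1] == v[-n])
    grp <- cumsum(c(TRUE, !same))
    starts <- which(!duplicated(grp))
    ends <- c(starts[-1] - 1L, n)
    keep <- !is.na(v[starts])
    if (!any(keep)) next
    lines <- sprintf("%s\t%d\t%d\t%s", chr,
                     ch$offset + starts[keep] - 1L,
                     ch$offset + ends[keep],
                     sprintf("%.17g", v[starts[keep]]))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read TSS records from a FANTOM5-style BED file
#'
#' Keeps entries whose name matches the `p1@gene` convention and takes the
#' gene-strand downstream edge of each interval as the TSS position
#' (0-based): the last base for + strand genes, the first base for - strand
#' genes.
#'
#' @param path BED file path.
#' @return data.frame `gene`, `tss_id`, `chrom`, `strand`, `pos`.
#' @export
read_tss_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- S4Vectors::mcols(gr)$name
  keep <- grepl("^p1@", nm)
  gr <- gr[keep]
  nm <- nm[keep]
  if (length(gr) == 0) stop_data("no p1@gene entries in ", path)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop_data("TSS BED entries must be stranded")
  pos <- ifelse(strand == "+",
                GenomicRanges::end(gr) - 1L,    # 0-based last base
                GenomicRanges::start(gr) - 1L)  # 0-based first base
  data.frame(gene = sub("^p1@", "", nm), tss_id = nm,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = strand, pos = as.integer(pos), stringsAsFactors = FALSE)
}

#' Signed sgRNA position relative to its gene's TSS
#'
#' The sgRNA position is the genomic coordinate of the 3' G of the NGG PAM;
#' distances are positive downstream of the TSS in the gene's orientation,
#' regardless of which strand the protospacer lies on.
#'
#' @param library sgRNA library data.frame with `gene`, `tss_id`,
#'   `pam_g3_pos`, `is_negctrl`.
#' @param tss TSS data.frame (`tss_id`, `strand`, `pos`).
#' @return data.frame `sgrna_id`, `gene`, `tss_id`, `rel_pos` for targeting
#'   sgRNAs.
#' @export
sgrna_rel_pos <- function(library, tss) {
  lib <- library[!library$is_negctrl, ]
  m <- match(lib$tss_id, tss$tss_id)
  if (any(is.na(m)))
    stop_data("sgRNA(s) reference unknown TSS: ",
              paste(utils::head(unique(lib$tss_id[is.na(m)]), 5), collapse = ", "))
  rel <- ifelse(tss$strand[m] == "+",
                lib$pam_g3_pos - tss$pos[m],
                tss$pos[m] - lib$pam_g3_pos)
  data.frame(sgrna_id = lib$sgrna_id, gene = lib$gene, tss_id = lib$tss_id,
             rel_pos = as.integer(rel), stringsAsFactors = FALSE)
}
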