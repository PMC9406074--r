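#' Generate a synthetic amplicon panel
#'
#' Builds a seeded, reproducible panel of hotspot amplicons of the kind used
#' for deep sequencing of plasma cfDNA in hepatocellular carcinoma: one
#' amplicon per target region, each with a forward primer (the 5' prefix of
#' the reference) and a reverse primer (the reverse complement of the 3'
#' suffix, i.e. the primer as sequenced from the opposite strand). Primer
#' prefixes are regenerated until every pair of primers in the panel differs
#' at more than `min_primer_dist` positions, so that demultiplexing with up
#' to three tolerated differences is unambiguous.
#'
#' @param n_amplicons Number of amplicons (>= 1).
#' @param length_range Two-element integer vector; amplicon lengths are drawn
#'   uniformly from this range. Default 185-216 bp, the usual size range for
#'   cfDNA hotspot amplicons.
#' @param genes Gene labels recycled across amplicons. The default five are
#'   the canonical HCC driver targets. A gene named `"TERT"` is treated as a
#'   promoter (noncoding) target; all others get a coding frame.
#' @param primer_len Primer length in bases (same for all primers).
#' @param min_primer_dist Minimum pairwise Hamming distance required between
#'   any two primers in the panel.
#' @param seed Integer seed; the same seed yields a byte-identical panel.
#' @param max_tries Bounded retries for the primer-separation constraint.
#' @return A tibble of class `pv_panel` with one row per amplicon and columns
#'   `amplicon_id`, `gene`, `reference_seq`, `forward_primer`,
#'   `reverse_primer`, `contig`, `anchor_start`, `anchor_strand`,
#'   `coding_frame` (integer 0-2, or `NA` for noncoding amplicons).
#' @export
#' @examples
#' panel <- pv_make_panel(5, seed = 7)
#' nchar(panel$reference_seq)
pv_make_panel <- function(n_amplicons,
                          length_range = c(185L, 216L),
                          genes = c("TERT", "TP53", "CTNNB1", "AXIN1", "ARID1A"),
                          primer_len = 22L,
                          min_primer_dist = 7L,
                          seed = 1L,
                          max_tries = 200L) {
  if (n_amplicons < 1L) abort("n_amplicons must be >= 1")
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || length_range[1] > length_range[2] ||
      length_range[1] < 100L || length_range[2] > 400L) {
    abort("length_range must be within [100, 400] and non-decreasing")
  }
  if (2L * primer_len >= length_range[1]) {
    abort("primers would overlap: 2 * primer_len must be < min amplicon length")
  }
  set.seed(as.integer(seed))
  gene <- rep_len(genes, n_amplicons)
  lens <- length_range[1] - 1L +
    sample.int(length_range[2] - length_range[1] + 1L, n_amplicons,
               replace = TRUE)

  draw_seq <- function(L) paste(sample(DNA_BASES, L, replace = TRUE),
                                collapse = "")
  ok <- FALSE
  for (try in seq_len(max_tries)) {
    refs <- vapply(lens, draw_seq, character(1))
    fwd <- substr(refs, 1L, primer_len)
    rev_as_seq <- pv_revcomp(substr(refs, nchar(refs) - primer_len + 1L,
                                    nchar(refs)))
    prim <- c(fwd, rev_as_seq)
    dmin <- Inf
    for (i in seq_along(prim)) {
      for (j in seq_along(prim)) {
        if (j <= i) next
        dmin <- min(dmin, pv_hamming(prim[i], prim[j]))
      }
    }
    if (length(prim) == 1L || dmin >= min_primer_dist) { ok <- TRUE; break }
  }
  if (!ok) {
    abort(sprintf(
      "could not satisfy primer separation (pairwise Hamming >= %d) in %d tries",
      min_primer_dist, max_tries))
  }

  panel <- tibble::tibble(
    amplicon_id = sprintf("AMP%02d_%s", seq_len(n_amplicons), gene),
    gene = gene,
    reference_seq = refs,
    forward_primer = substr(refs, 1L, primer_len),
    reverse_primer = pv_revcomp(substr(refs, nchar(refs) - primer_len + 1L,
                                       nchar(refs))),
    contig = sprintf("ctg%02d", seq_len(n_amplicons)),
    anchor_start = sample(1e6:2e6, n_amplicons),
    anchor_strand = sample(c("+", "-"), n_amplicons, replace = TRUE),
    coding_frame = ifelse(gene == "TERT", NA_integer_,
                          sample(0:2, n_amplicons, replace = TRUE))
  )
  class(panel) <- c("pv_panel", class(panel))
  pv_validate_panel(panel)
  panel
}

#' Validate an amplicon panel
#'
#' Checks the structural invariants a panel must satisfy before use:
#' DNA alphabet, length bounds, and that each forward primer is a prefix of
#' the reference while each reverse primer is the reverse complement of its
#' suffix.
#'
#' @param panel A panel tibble (see [pv_make_panel()] for the schema).
#' @return The validated panel, invisibly classed as `pv_panel`.
#' @export
pv_validate_panel <- function(panel) {
  need <- c("amplicon_id", "gene", "reference_seq", "forward_primer",
            "reverse_primer", "contig", "anchor_start", "anchor_strand",
            "coding_frame")
  miss <- setdiff(need, names(panel))
  if (length(miss)) abort(paste("panel is missing columns:",
                                paste(miss, collapse = ", ")))
  if (anyDuplicated(panel$amplicon_id))
    abort("amplicon_id values must be unique")
  pv_check_dna(panel$reference_seq, "reference_seq")
  pv_check_dna(panel$forward_primer, "forward_primer")
  pv_check_dna(panel$reverse_primer, "reverse_primer")
  L <- nchar(panel$reference_seq)
  if (any(L < 100L | L > 400L))
    abort("reference_seq lengths must lie in [100, 400]")
  if (!all(startsWith(panel$reference_seq, panel$forward_primer)))
    abort("every forward_primer must be a prefix of its reference_seq")
  tail_ok <- vapply(seq_len(nrow(panel)), function(i) {
    lp <- nchar(panel$reverse_primer[i])
    suf <- unname(substr(panel$reference_seq[i], L[i] - lp + 1L, L[i]))
    identical(unname(pv_revcomp(panel$reverse_primer[i])), suf)
  }, logical(1))
  if (!all(tail_ok))
    abort("every reverse_primer must be the reverse complement of its reference_seq suffix")
  if (!all(panel$anchor_strand %in% c("+", "-")))
    abort("anchor_strand must be '+' or '-'")
  if (!all(is.na(panel$coding_frame) | panel$coding_frame %in% 0:2))
    abort("coding_frame must be 0, 1, 2 or NA (noncoding)")
  if (!inherits(panel, "pv_panel")) class(panel) <- c("pv_panel", class(panel))
  invisible(panel)
}

#' Write / read a panel as FASTA plus metadata TSV
#'
#' The reference sequences go to FASTA (one record per amplicon, named by
#' `amplicon_id`); all other columns go to a tab-separated metadata table.
#'
#' @param panel A validated panel.
#' @param fasta,tsv Output (or input) paths.
#' @return `pv_write_panel()` returns the paths invisibly;
#'   `pv_read_panel()` returns the panel tibble.
#' @export
pv_write_panel <- function(panel, fasta, tsv) {
  pv_validate_panel(panel)
  seqs <- Biostrings::DNAStringSet(panel$reference_seq)
  names(seqs) <- panel$amplicon_id
  Biostrings::writeXStringSet(seqs, fasta, width = 80L)
  meta <- dplyr::select(as.data.frame(panel), -"reference_seq")
  write.table(meta, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, tsv = tsv))
}

#' @rdname pv_write_panel
#' @export
pv_read_panel <- function(fasta, tsv) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  meta <- tibble::as_tibble(read.delim(tsv, stringsAsFactors = FALSE))
  meta$coding_frame <- suppressWarnings(as.integer(meta$coding_frame))
  idx <- match(meta$amplicon_id, names(seqs))
  if (anyNA(idx)) abort("FASTA and metadata amplicon_id sets disagree")
  panel <- dplyr::mutate(meta,
                         reference_seq = unname(as.character(seqs)[idx]),
                         .after = "gene")
  pv_validate_panel(tibble::as_tibble(panel))
}
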