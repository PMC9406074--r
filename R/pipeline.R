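#' Merge paired-end reads into full amplicons
#'
#' Reverse-complements read 2, scans candidate overlaps from the longest down
#' to `min_overlap`, and accepts the longest overlap whose mismatch fraction
#' is at most `max_mismatch_frac` (a fraction exactly at the threshold still
#' merges; `N` counts as a mismatch). Disagreeing overlap bases resolve to
#' the higher-quality base (tie: read 1's base); the merged quality at each
#' overlap position is the maximum of the two mates.
#'
#' @param reads Tibble with columns `read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2` (see [pv_read_fastq_pair()]).
#' @param params A [pv_pipeline_params()] object.
#' @return The input tibble with columns `merged` (logical), `seq`, `qual`,
#'   `overlap_len`, `overlap_mismatches` (NA where no overlap qualified).
#' @export
pv_merge_pairs <- function(reads, params = pv_pipeline_params()) {
  if (!nrow(reads)) {
    return(dplyr::mutate(reads, merged = logical(0), seq = character(0),
                         qual = character(0), overlap_len = integer(0),
                         overlap_mismatches = integer(0)))
  }
  if (any(!nzchar(reads$seq1)) || any(!nzchar(reads$seq2)))
    abort("empty sequences cannot be merged")
  pv_check_dna(reads$seq1, "seq1", allow_n = TRUE)
  pv_check_dna(reads$seq2, "seq2", allow_n = TRUE)
  res <- merge_pairs_cpp(reads$seq1, reads$qual1,
                         pv_revcomp(reads$seq2), pv_reverse_str(reads$qual2),
                         params$min_overlap, params$max_mismatch_frac)
  dplyr::mutate(reads,
                merged = res$merged, seq = res$seq, qual = res$qual,
                overlap_len = res$overlap_len,
                overlap_mismatches = res$overlap_mismatches)
}

#' Quality-filter merged reads
#'
#' Discards a merged read when the fraction of its bases below the Phred
#' threshold is greater than or equal to `max_low_q_frac` (so with the
#' defaults, a read with exactly 5% of bases below Q30 is discarded).
#' `N` bases count as below threshold.
#'
#' @param merged Output of [pv_merge_pairs()] (rows with `merged == FALSE`
#'   are left untouched, `quality_pass = NA`).
#' @inheritParams pv_merge_pairs
#' @return Input tibble plus `n_low_q`, `frac_low_q` and `quality_pass`.
#' @export
pv_quality_filter <- function(merged, params = pv_pipeline_params()) {
  n <- nrow(merged)
  n_low <- rep(NA_integer_, n)
  frac <- rep(NA_real_, n)
  ok <- which(!is.na(merged$merged) & merged$merged)
  if (length(ok)) {
    has_n <- grepl("N", merged$seq[ok], fixed = TRUE)
    n_low[ok] <- vapply(seq_along(ok), function(j) {
      i <- ok[j]
      q <- pv_phred_decode(merged$qual[i])
      low <- q < params$q_threshold
      if (has_n[j]) {
        low <- low | strsplit(merged$seq[i], "")[[1]] == "N"
      }
      sum(low)
    }, integer(1))
    frac[ok] <- n_low[ok] / nchar(merged$qual[ok])
  }
  dplyr::mutate(merged, n_low_q = n_low, frac_low_q = frac,
                quality_pass = frac < params$max_low_q_frac)
}

#' Demultiplex merged reads to amplicons by primer matching
#'
#' Compares each read's 5' prefix and 3' suffix (the read is tried in both
#' orientations) against every amplicon's forward primer and reverse-primer
#' complement using Hamming distance. The candidate minimising total primer
#' mismatches wins provided each primer matches within `max_primer_diff`
#' differences; ties between different amplicons are left unassigned as
#' ambiguous. Assigned reads are reported primer-trimmed and reoriented to
#' the forward (reference) orientation.
#'
#' @param merged Tibble with `seq`/`qual` columns (quality-passing merged
#'   reads; rows failing earlier stages are passed through unassigned).
#' @param panel Amplicon panel.
#' @inheritParams pv_merge_pairs
#' @return Input tibble plus `amplicon_id`, `strand`, `primer_mismatches`,
#'   `trimmed_seq`, `trimmed_qual` and `demux_status` (one of `assigned`,
#'   `no_match`, `ambiguous`, `too_short`, `not_evaluated`).
#' @export
pv_demultiplex <- function(merged, panel, params = pv_pipeline_params()) {
  pv_validate_panel(panel)
  n <- nrow(merged)
  amplicon_id <- rep(NA_character_, n)
  strand <- rep(NA_character_, n)
  mism <- rep(NA_integer_, n)
  tseq <- rep(NA_character_, n)
  tqual <- rep(NA_character_, n)
  status <- rep("not_evaluated", n)

  eligible <- !is.na(merged$seq)
  if ("quality_pass" %in% names(merged)) {
    eligible <- eligible & !is.na(merged$quality_pass) & merged$quality_pass
  }
  idx <- which(eligible)
  if (length(idx)) {
    seqs <- merged$seq[idx]
    rcs <- pv_revcomp(seqs)
    end_seq <- pv_revcomp(panel$reverse_primer)
    res <- demux_cpp(seqs, rcs, panel$forward_primer, end_seq,
                     params$max_primer_diff)
    st <- c("assigned", "no_match", "ambiguous", "too_short")[res$status + 1L]
    status[idx] <- st
    hit <- res$amp > 0L
    if (any(hit)) {
      ai <- res$amp[hit]
      amplicon_id[idx[hit]] <- panel$amplicon_id[ai]
      strand[idx[hit]] <- c("forward", "reverse")[res$strand[hit]]
      mism[idx[hit]] <- res$mism5[hit] + res$mism3[hit]
      oriented <- ifelse(res$strand[hit] == 1L, seqs[hit], rcs[hit])
      qual <- merged$qual[idx[hit]]
      oq <- ifelse(res$strand[hit] == 1L, qual, pv_reverse_str(qual))
      lp <- nchar(panel$forward_primer)[ai]
      le <- nchar(panel$reverse_primer)[ai]
      tseq[idx[hit]] <- substr(oriented, lp + 1L, nchar(oriented) - le)
      tqual[idx[hit]] <- substr(oq, lp + 1L, nchar(oq) - le)
    }
  }
  dplyr::mutate(merged, amplicon_id = amplicon_id, strand = strand,
                primer_mismatches = mism, trimmed_seq = tseq,
                trimmed_qual = tqual, demux_status = status)
}

#' Run the full read-level stage: merge, quality-filter, demultiplex
#'
#' Applies the three read-level steps in their canonical order and reports
#' per-category counts. Every input pair lands in exactly one report
#' category: merge failure, quality discard, unassigned (no match, ambiguous
#' or too short) or assigned.
#'
#' @param reads Either a reads tibble (`read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`) or a length-2 character vector of FASTQ paths (R1, R2).
#' @param panel Amplicon panel.
#' @inheritParams pv_merge_pairs
#' @return A list of class `pv_read_stage`: `reads` (the full annotated
#'   tibble), `assigned` (only assigned reads, primer-trimmed), `report`
#'   (one-row tibble of stage counts) and `per_amplicon` (assigned counts by
#'   amplicon and strand).
#' @export
pv_run_read_stage <- function(reads, panel, params = pv_pipeline_params()) {
  if (is.character(reads)) {
    if (length(reads) != 2L) abort("give FASTQ paths as c(r1, r2)")
    reads <- pv_read_fastq_pair(reads[1], reads[2])
  }
  if (!nrow(reads)) {
    rep0 <- tibble::tibble(pairs_in = 0L, merged = 0L, merge_failures = 0L,
                           quality_discards = 0L, assigned = 0L,
                           unassigned = 0L)
    out <- list(reads = reads, assigned = reads[0, ], report = rep0,
                per_amplicon = tibble::tibble(amplicon_id = character(0),
                                              strand = character(0),
                                              n = integer(0)))
    class(out) <- "pv_read_stage"
    return(out)
  }
  x <- pv_merge_pairs(reads, params)
  x <- pv_quality_filter(x, params)
  x <- pv_demultiplex(x, panel, params)

  report <- tibble::tibble(
    pairs_in = nrow(x),
    merged = sum(x$merged),
    merge_failures = sum(!x$merged),
    quality_discards = sum(x$merged & !x$quality_pass),
    assigned = sum(x$demux_status == "assigned"),
    unassigned = sum(x$merged & x$quality_pass &
                       x$demux_status != "assigned")
  )
  stopifnot(report$pairs_in == report$merge_failures +
              report$quality_discards + report$assigned + report$unassigned)
  assigned <- dplyr::filter(x, .data$demux_status == "assigned")
  per_amplicon <- dplyr::count(assigned, .data$amplicon_id, .data$strand)
  out <- list(reads = x, assigned = assigned, report = report,
              per_amplicon = per_amplicon)
  class(out) <- "pv_read_stage"
  out
}

#' @export
print.pv_read_stage <- function(x, ...) {
  cat("<pv_read_stage>\n")
  print(x$report)
  invisible(x)
}
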