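#' Collapse trimmed reads into haplotypes
#'
#' Groups assigned, primer-trimmed, forward-oriented reads by exact sequence
#' within each amplicon/strand and computes counts and relative abundances
#' (count over all reads assigned to that amplicon and strand). Haplotypes
#' are ordered by descending abundance, ties broken lexicographically.
#'
#' @param assigned Tibble of assigned reads with columns `amplicon_id`,
#'   `strand`, `trimmed_seq` (e.g. the `assigned` element of
#'   [pv_run_read_stage()]).
#' @return Tibble with `amplicon_id`, `strand`, `seq`, `count`, `abundance`.
#' @export
pv_collapse <- function(assigned) {
  need <- c("amplicon_id", "strand", "trimmed_seq")
  miss <- setdiff(need, names(assigned))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  if (!nrow(assigned)) {
    return(tibble::tibble(amplicon_id = character(0), strand = character(0),
                          seq = character(0), count = integer(0),
                          abundance = numeric(0)))
  }
  assigned |>
    dplyr::count(.data$amplicon_id, .data$strand, seq = .data$trimmed_seq,
                 name = "count") |>
    dplyr::group_by(.data$amplicon_id, .data$strand) |>
    dplyr::mutate(abundance = .data$count / sum(.data$count)) |>
    dplyr::arrange(dplyr::desc(.data$abundance), .data$seq,
                   .by_group = TRUE) |>
    dplyr::ungroup()
}

#' Strand-concordance filter for haplotypes
#'
#' Keeps a haplotype sequence only if its abundance is at least
#' `min_hap_abundance` on the forward strand and at least
#' `min_hap_abundance` on the reverse strand (abundances exactly at the
#' threshold survive). Surviving haplotypes get a count-weighted combined
#' abundance, `(fwd_count + rev_count) / (fwd_total + rev_total)`, where the
#' totals are all reads assigned to the amplicon on each strand before any
#' haplotype filtering. An amplicon with one strand entirely missing yields
#' no consensus haplotypes and a warning (amplicon dropout).
#'
#' @param haplotypes Output of [pv_collapse()] (both strands, one or more
#'   amplicons).
#' @param params A [pv_filter_params()] object.
#' @return Tibble with `amplicon_id`, `seq`, `fwd_count`, `rev_count`,
#'   `fwd_abundance`, `rev_abundance`, `combined_abundance`, sorted by
#'   descending combined abundance within amplicon.
#' @export
pv_strand_filter <- function(haplotypes, params = pv_filter_params()) {
  empty <- tibble::tibble(amplicon_id = character(0), seq = character(0),
                          fwd_count = integer(0), rev_count = integer(0),
                          fwd_abundance = numeric(0),
                          rev_abundance = numeric(0),
                          combined_abundance = numeric(0))
  if (!nrow(haplotypes)) return(empty)
  out <- vector("list", 0L)
  for (amp in unique(haplotypes$amplicon_id)) {
    h <- haplotypes[haplotypes$amplicon_id == amp, ]
    fwd <- h[h$strand == "forward", ]
    rev <- h[h$strand == "reverse", ]
    if (!nrow(fwd) || !nrow(rev)) {
      warn(sprintf("amplicon %s has no reads on the %s strand; dropped", amp,
                   if (nrow(fwd)) "reverse" else "forward"),
           class = "pv_amplicon_dropout")
      next
    }
    fwd_total <- sum(fwd$count)
    rev_total <- sum(rev$count)
    j <- dplyr::inner_join(
      dplyr::select(fwd, "seq", fwd_count = "count", fwd_abundance = "abundance"),
      dplyr::select(rev, "seq", rev_count = "count", rev_abundance = "abundance"),
      by = "seq")
    j <- dplyr::filter(j, .data$fwd_abundance >= params$min_hap_abundance,
                       .data$rev_abundance >= params$min_hap_abundance)
    if (!nrow(j)) next
    j <- dplyr::mutate(j, amplicon_id = amp,
                       combined_abundance = (.data$fwd_count + .data$rev_count) /
                         (fwd_total + rev_total), .before = 1)
    out[[length(out) + 1L]] <- j
  }
  if (!length(out)) return(empty)
  dplyr::bind_rows(out) |>
    dplyr::relocate("amplicon_id", "seq") |>
    dplyr::arrange(.data$amplicon_id, dplyr::desc(.data$combined_abundance),
                   .data$seq)
}
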