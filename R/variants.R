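#' Call single-nucleotide variants from consensus haplotypes
#'
#' Compares each strand-concordant consensus haplotype against the amplicon
#' reference and aggregates, per position and alternate allele, the combined
#' abundances of the haplotypes carrying that allele, normalised by the total
#' abundance of the retained consensus haplotypes (so the per-position allele
#' frequencies, reference allele included, sum to 1). Calls whose aggregate
#' frequency falls below `min_variant_freq` are dropped (a frequency exactly
#' at the threshold survives). Haplotypes whose length differs from the
#' reference (putative indels, outside the SNV-only scope) are excluded from
#' calling and tallied in the `excluded_length_mismatch` attribute.
#'
#' Each call is annotated with a genomic label derived from the amplicon's
#' anchor ([pv_label_genomic()]), a known/novel flag looked up in a local
#' variant catalog, and its coding consequence (`nonsynonymous`,
#' `synonymous`, or `noncoding` for amplicons without a coding frame).
#'
#' @param consensus Output of [pv_strand_filter()].
#' @param panel Amplicon panel.
#' @param params A [pv_filter_params()] object.
#' @param catalog Optional catalog tibble (see [pv_read_catalog()]) with
#'   columns `contig`, `genomic_pos`, `ref`, `alt` and optionally `alias`.
#' @return Tibble with one row per called variant: `amplicon_id`, `gene`,
#'   `position`, `ref_base`, `alt_base`, `frequency`, `genomic_label`,
#'   `alias`, `known`, `synonymy`.
#' @export
pv_call_variants <- function(consensus, panel, params = pv_filter_params(),
                             catalog = NULL) {
  pv_validate_panel(panel)
  empty <- tibble::tibble(amplicon_id = character(0), gene = character(0),
                          position = integer(0), ref_base = character(0),
                          alt_base = character(0), frequency = numeric(0),
                          genomic_label = character(0), alias = character(0),
                          known = logical(0), synonymy = character(0))
  attr(empty, "excluded_length_mismatch") <- 0L
  if (!nrow(consensus)) return(empty)

  excluded <- 0L
  rows <- vector("list", 0L)
  for (amp in unique(consensus$amplicon_id)) {
    a <- panel[panel$amplicon_id == amp, ]
    if (!nrow(a)) abort(sprintf("consensus references unknown amplicon %s", amp))
    trimmed_ref <- substr(a$reference_seq, nchar(a$forward_primer) + 1L,
                          nchar(a$reference_seq) - nchar(a$reverse_primer))
    h <- consensus[consensus$amplicon_id == amp, ]
    len_ok <- nchar(h$seq) == nchar(trimmed_ref)
    excluded <- excluded + sum(!len_ok)
    h <- h[len_ok, ]
    if (!nrow(h)) next
    pv_check_dna(h$seq, "haplotype seq", allow_n = FALSE)
    ref_chars <- strsplit(trimmed_ref, "")[[1]]
    hmat <- matrix(unlist(strsplit(h$seq, "")), nrow = nrow(h), byrow = TRUE)
    # Frequencies are relative to the retained consensus haplotypes, so the
    # per-position allele frequencies (reference included) sum to exactly 1
    # and sub-threshold error haplotypes do not bias calls downward.
    total_ab <- sum(h$combined_abundance)
    for (pos in seq_along(ref_chars)) {
      col <- hmat[, pos]
      diffs <- col != ref_chars[pos]
      if (!any(diffs)) next
      for (alt in unique(col[diffs])) {
        freq <- sum(h$combined_abundance[col == alt]) / total_ab
        if (freq < params$min_variant_freq) next
        rows[[length(rows) + 1L]] <- tibble::tibble(
          amplicon_id = amp, gene = a$gene,
          position = pos + nchar(a$forward_primer),  # 1-based in reference_seq
          ref_base = ref_chars[pos], alt_base = alt, frequency = freq)
      }
    }
  }
  if (!length(rows)) {
    attr(empty, "excluded_length_mismatch") <- excluded
    return(empty)
  }
  calls <- dplyr::bind_rows(rows)
  lab <- pv_label_genomic(calls, panel, catalog = catalog)
  calls <- dplyr::bind_cols(calls, lab)
  calls$synonymy <- vapply(seq_len(nrow(calls)), function(i) {
    a <- panel[panel$amplicon_id == calls$amplicon_id[i], ]
    pv_synonymy(a$reference_seq, calls$position[i], calls$alt_base[i],
                a$coding_frame)
  }, character(1))
  calls <- dplyr::arrange(calls, .data$amplicon_id, .data$position,
                          .data$alt_base)
  attr(calls, "excluded_length_mismatch") <- excluded
  calls
}

#' Map amplicon-local calls to genomic labels
#'
#' Projects a position within an amplicon's reference onto the genome using
#' the amplicon's anchor. For a forward-anchored amplicon the genomic
#' position is `anchor_start + position - 1` and alleles are reported as-is;
#' for a reverse-anchored amplicon the position is
#' `anchor_start + (reference_length - position)` and alleles are
#' complemented. The label is rendered `contig:pos ref>alt`; when a catalog
#' carries an alias for the variant (e.g. `C228T (-124)`), the alias is
#' attached and the variant flagged as known. Amplicons without an anchor
#' fall back to an amplicon-local label.
#'
#' @param calls Tibble with `amplicon_id`, `position`, `ref_base`,
#'   `alt_base`.
#' @param panel Amplicon panel.
#' @param catalog Optional catalog tibble.
#' @return Tibble with `contig`, `genomic_pos`, `genomic_ref`, `genomic_alt`,
#'   `genomic_label`, `alias`, `known` (row-aligned with `calls`).
#' @export
pv_label_genomic <- function(calls, panel, catalog = NULL) {
  idx <- match(calls$amplicon_id, panel$amplicon_id)
  if (anyNA(idx)) abort("calls reference amplicons absent from the panel")
  a <- panel[idx, ]
  L <- nchar(a$reference_seq)
  fwd <- is.na(a$anchor_strand) | a$anchor_strand == "+"
  gpos <- ifelse(fwd, a$anchor_start + calls$position - 1L,
                 a$anchor_start + (L - calls$position))
  gref <- ifelse(fwd, calls$ref_base, pv_complement_base(calls$ref_base))
  galt <- ifelse(fwd, calls$alt_base, pv_complement_base(calls$alt_base))
  no_anchor <- is.na(a$contig) | is.na(a$anchor_start)
  label <- ifelse(no_anchor,
                  sprintf("%s:%d %s>%s", calls$amplicon_id, calls$position,
                          calls$ref_base, calls$alt_base),
                  sprintf("%s:%d %s>%s", a$contig, gpos, gref, galt))
  alias <- rep(NA_character_, nrow(calls))
  known <- rep(FALSE, nrow(calls))
  if (!is.null(catalog) && nrow(catalog)) {
    key <- paste(a$contig, gpos, gref, galt)
    ckey <- paste(catalog$contig, catalog$genomic_pos, catalog$ref,
                  catalog$alt)
    m <- match(key, ckey)
    known <- !is.na(m) & !no_anchor
    if ("alias" %in% names(catalog)) alias[known] <- catalog$alias[m[known]]
    label <- ifelse(known & !is.na(alias), paste0(label, " [", alias, "]"),
                    label)
  }
  tibble::tibble(contig = ifelse(no_anchor, NA_character_, a$contig),
                 genomic_pos = ifelse(no_anchor, NA_integer_, gpos),
                 genomic_ref = ifelse(no_anchor, NA_character_, gref),
                 genomic_alt = ifelse(no_anchor, NA_character_, galt),
                 genomic_label = label, alias = alias, known = known)
}

# Coding consequence of a substitution given the amplicon's frame.
# frame f (0-2): the first complete codon starts at reference position f+1.
# Positions before the first codon or in a trailing partial codon are
# reported "noncoding", as is everything on amplicons without a frame
# (e.g. promoter targets).
pv_synonymy <- function(ref_seq, position, alt_base, coding_frame) {
  if (is.na(coding_frame)) return("noncoding")
  f <- as.integer(coding_frame)
  if (position <= f) return("noncoding")
  codon_start <- f + 1L + 3L * ((position - f - 1L) %/% 3L)
  if (codon_start + 2L > nchar(ref_seq)) return("noncoding")
  codon <- substr(ref_seq, codon_start, codon_start + 2L)
  off <- position - codon_start + 1L
  alt_codon <- codon
  substr(alt_codon, off, off) <- alt_base
  gc <- Biostrings::GENETIC_CODE
  if (identical(unname(gc[codon]), unname(gc[alt_codon]))) "synonymous"
  else "nonsynonymous"
}

#' Read a local variant catalog
#'
#' A catalog is a tab-separated table of previously reported variants used to
#' flag calls as known and to attach field aliases (such as the TERT promoter
#' `C228T (-124)` naming). Required columns: `gene`, `contig`, `genomic_pos`,
#' `ref`, `alt`; optional: `alias`. A small synthetic example catalog in the
#' style of the HCC hotspot literature ships with the package
#' (`system.file("extdata", "synthetic_hotspots_catalog.tsv",
#' package = "plasmavar")`); real analyses should supply their own export.
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
pv_read_catalog <- function(path) {
  x <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  need <- c("gene", "contig", "genomic_pos", "ref", "alt")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste("catalog is missing columns:",
                                paste(miss, collapse = ", ")))
  x
}

#' Summarise one plasma sample into a mutation profile
#'
#' Computes the per-sample burden quantities used downstream: the number of
#' counted mutations (nonsynonymous and noncoding calls; synonymous calls are
#' excluded), the number of distinct mutated genes among them, and the cfDNA
#' concentration. Calls are deduplicated by (amplicon, position, alt).
#'
#' @param calls Variant calls ([pv_call_variants()] output; may be empty).
#' @param cfdna_conc cfDNA concentration in ng/uL (>= 0).
#' @param sample_id Optional sample label.
#' @return A one-row tibble with `sample_id`, `cfdna_conc`, `n_mutations`,
#'   `n_genes` and a `calls` list-column holding the counted calls.
#' @export
pv_sample_profile <- function(calls, cfdna_conc, sample_id = NA_character_) {
  if (length(cfdna_conc) != 1L || is.na(cfdna_conc) || cfdna_conc < 0)
    abort("cfdna_conc must be a single non-negative number")
  if (nrow(calls)) {
    calls <- dplyr::distinct(calls, .data$amplicon_id, .data$position,
                             .data$alt_base, .keep_all = TRUE)
  }
  counted <- calls[calls$synonymy %in% c("nonsynonymous", "noncoding"), ,
                   drop = FALSE]
  tibble::tibble(sample_id = sample_id,
                 cfdna_conc = cfdna_conc,
                 n_mutations = nrow(counted),
                 n_genes = dplyr::n_distinct(counted$gene),
                 calls = list(counted))
}

#' Write variant calls as TSV and minimal VCF 4.2
#'
#' The VCF carries one record per call with `AF` (aggregate frequency),
#' `GENE` and `KNOWN` INFO fields; calls without a genomic anchor use the
#' amplicon id as CHROM and the amplicon-local position.
#'
#' @param calls Variant calls tibble.
#' @param path Output path (`.vcf`).
#' @param sample_id Optional sample name recorded in the header.
#' @return The path, invisibly.
#' @export
pv_write_vcf <- function(calls, path, sample_id = "sample") {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=plasmavar %s", as.character(packageVersion("plasmavar"))),
           sprintf("##sample=%s", sample_id),
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Aggregate variant frequency\">",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Panel gene\">",
           "##INFO=<ID=KNOWN,Number=0,Type=Flag,Description=\"Present in local variant catalog\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(calls)) {
    chrom <- ifelse(is.na(calls$contig), calls$amplicon_id, calls$contig)
    pos <- ifelse(is.na(calls$genomic_pos), calls$position, calls$genomic_pos)
    ref <- ifelse(is.na(calls$genomic_ref), calls$ref_base, calls$genomic_ref)
    alt <- ifelse(is.na(calls$genomic_alt), calls$alt_base, calls$genomic_alt)
    id <- ifelse(is.na(calls$alias), ".", calls$alias)
    info <- sprintf("AF=%.6g;GENE=%s%s", calls$frequency, calls$gene,
                    ifelse(calls$known, ";KNOWN", ""))
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                    chrom, as.integer(pos), id, ref, alt, info)
  } else {
    body <- character(0)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Run haplotype collapsing and variant calling on assigned reads
#'
#' Convenience wrapper chaining [pv_collapse()], [pv_strand_filter()] and
#' [pv_call_variants()].
#'
#' @param assigned Assigned reads (see [pv_run_read_stage()]).
#' @param panel Amplicon panel.
#' @param params A [pv_filter_params()] object.
#' @param catalog Optional variant catalog.
#' @return A list with `haplotypes`, `consensus` and `calls`.
#' @export
pv_call_stage <- function(assigned, panel, params = pv_filter_params(),
                          catalog = NULL) {
  haps <- pv_collapse(assigned)
  cons <- pv_strand_filter(haps, params)
  calls <- pv_call_variants(cons, panel, params, catalog = catalog)
  list(haplotypes = haps, consensus = cons, calls = calls)
}
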