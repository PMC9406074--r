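# hand-built one-amplicon panel with controllable coding frame
toy_panel <- function(frame = 0L, strand = "+", L = 120L, seed = 42,
                      gene = "TP53") {
  set.seed(seed)
  ref <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
  tibble::tibble(
    amplicon_id = "T1", gene = gene, reference_seq = ref,
    forward_primer = substr(ref, 1, 20),
    reverse_primer = oracle_revcomp(substr(ref, L - 19, L)),
    contig = "chrT", anchor_start = 5000L, anchor_strand = strand,
    coding_frame = frame)
}

cons_tbl <- function(panel, seqs, abundances) {
  tibble::tibble(amplicon_id = panel$amplicon_id, seq = seqs,
                 fwd_count = as.integer(round(abundances * 5000)),
                 rev_count = as.integer(round(abundances * 5000)),
                 fwd_abundance = abundances, rev_abundance = abundances,
                 combined_abundance = abundances)
}

trimmed_ref <- function(panel) {
  substr(panel$reference_seq, nchar(panel$forward_primer) + 1,
         nchar(panel$reference_seq) - nchar(panel$reverse_primer))
}

test_that("variant frequencies aggregate over carrying haplotypes", {
  panel <- toy_panel()
  tr <- trimmed_ref(panel)
  # two distinct haplotypes carry the same alt at trimmed position 15
  alt_at <- function(s, pos, b) { substr(s, pos, pos) <- b; s }
  base15 <- substr(tr, 15, 15)
  alt <- setdiff(c("A", "C", "G", "T"), base15)[1]
  h1 <- alt_at(tr, 15, alt)
  h2 <- alt_at(alt_at(tr, 15, alt), 40,
               setdiff(c("A", "C", "G", "T"), substr(tr, 40, 40))[1])
  cons <- cons_tbl(panel, c(tr, h1, h2), c(0.965, 0.02, 0.015))
  calls <- pv_call_variants(cons, panel)
  main <- calls[calls$position == 15 + 20, ]
  expect_equal(nrow(main), 1L)
  expect_equal(main$frequency, 0.035)
  expect_equal(main$ref_base, base15)
  expect_equal(main$alt_base, alt)

  # all-reference consensus: zero calls
  expect_equal(nrow(pv_call_variants(cons_tbl(panel, tr, 1), panel)), 0L)

  # aggregate below 1% is not called
  cons2 <- cons_tbl(panel, c(tr, h1), c(0.992, 0.008))
  expect_equal(nrow(pv_call_variants(cons2, panel)), 0L)
  # ... and exactly 1% survives (strict "below")
  cons3 <- cons_tbl(panel, c(tr, h1), c(0.99, 0.01))
  expect_equal(nrow(pv_call_variants(cons3, panel)), 1L)
})

test_that("per-position allele frequencies (incl. reference) sum to one", {
  panel <- toy_panel()
  tr <- trimmed_ref(panel)
  alt_at <- function(s, pos, b) { substr(s, pos, pos) <- b; s }
  h1 <- alt_at(tr, 10, "A"); h1 <- if (h1 == tr) alt_at(tr, 10, "C") else h1
  h2 <- alt_at(tr, 10, setdiff(c("A", "C", "G", "T"),
                               c(substr(tr, 10, 10), substr(h1, 10, 10)))[1])
  cons <- cons_tbl(panel, c(tr, h1, h2), c(0.90, 0.06, 0.04))
  calls <- pv_call_variants(cons, panel)
  p10 <- calls[calls$position == 30, ]
  expect_equal(sum(p10$frequency) + 0.90 / sum(cons$combined_abundance), 1,
               tolerance = 1e-12)
})

test_that("calls match per-read allele counting on simulated reads", {
  panel <- pv_make_panel(1, seed = 121)
  pos <- nchar(panel$forward_primer) + c(12L, 55L)
  refb <- substr(panel$reference_seq, pos, pos)
  alts <- vapply(refb, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                 character(1))
  specs <- pv_variant_specs(panel, panel$amplicon_id, pos, alts,
                            c(0.20, 0.05))
  sim <- pv_simulate_reads(panel, specs, depth_per_amplicon = 2000,
                           substitution_error_rate = 0.002, seed = 13)
  stage <- pv_run_read_stage(sim$reads, panel)
  res <- pv_call_stage(stage$assigned, panel)
  orc <- oracle_variant_freqs(stage$assigned$trimmed_seq,
                              res$consensus$seq,
                              trimmed_ref(panel))
  orc <- orc[order(orc$position, orc$alt), ]
  orc <- orc[orc$frequency >= 0.01, ]
  calls <- res$calls
  expect_equal(nrow(calls), nrow(orc))
  expect_equal(calls$position - nchar(panel$forward_primer), orc$position)
  expect_equal(calls$alt_base, orc$alt)
  expect_equal(calls$frequency, orc$frequency, tolerance = 1e-12)
})

test_that("genomic labels are strand-aware and pick up catalog aliases", {
  # forward anchor: position 10 from anchor 1295219 -> 1295228
  panel <- toy_panel(strand = "+")
  panel$contig <- "chr5"
  panel$anchor_start <- 1295219L
  calls <- tibble::tibble(amplicon_id = "T1", position = 10L,
                          ref_base = substr(panel$reference_seq, 10, 10),
                          alt_base = "A")
  if (calls$ref_base == "A") calls$alt_base <- "C"
  lab <- pv_label_genomic(calls, panel)
  expect_equal(lab$genomic_pos, 1295228L)
  expect_equal(lab$genomic_ref, calls$ref_base)
  expect_false(lab$known)

  # catalog lookup attaches the field alias
  catalog <- tibble::tibble(gene = "TERT", contig = "chr5",
                            genomic_pos = 1295228L, ref = calls$ref_base,
                            alt = calls$alt_base, alias = "C228T (-124)")
  lab2 <- pv_label_genomic(calls, panel, catalog)
  expect_true(lab2$known)
  expect_match(lab2$genomic_label, "C228T")

  # reverse anchor: complemented alleles, mirrored position
  panelr <- toy_panel(strand = "-")
  L <- nchar(panelr$reference_seq)
  callr <- tibble::tibble(amplicon_id = "T1", position = 10L,
                          ref_base = substr(panelr$reference_seq, 10, 10),
                          alt_base = setdiff(c("A", "C", "G", "T"),
                                             substr(panelr$reference_seq, 10, 10))[1])
  labr <- pv_label_genomic(callr, panelr)
  expect_equal(labr$genomic_pos, panelr$anchor_start + (L - 10L))
  expect_equal(labr$genomic_ref, oracle_revcomp(callr$ref_base))
  expect_equal(labr$genomic_alt, oracle_revcomp(callr$alt_base))
})

test_that("coding consequences follow the genetic code and frame", {
  # frame 0, engineered codons: reference TTT at positions 21-23 (first
  # in-frame codon after the primer is irrelevant: frame is over the whole
  # reference)
  panel <- toy_panel(frame = 0L)
  ref <- panel$reference_seq
  # position 24 starts codon 8 (frame 0): positions 22-24 form codon
  codon_start <- 22L
  substr(ref, codon_start, codon_start + 2) <- "TTT"
  panel$reference_seq <- ref
  panel$forward_primer <- substr(ref, 1, 20)
  panel$reverse_primer <- oracle_revcomp(substr(ref, nchar(ref) - 19,
                                                nchar(ref)))
  # TTT -> TTC: phenylalanine either way (synonymous)
  expect_equal(plasmavar:::pv_synonymy(ref, codon_start + 2L, "C", 0L),
               "synonymous")
  # TTT -> ATT: Phe -> Ile (nonsynonymous)
  expect_equal(plasmavar:::pv_synonymy(ref, codon_start, "A", 0L),
               "nonsynonymous")
  # promoter amplicon: noncoding
  expect_equal(plasmavar:::pv_synonymy(ref, 30L, "A", NA_integer_),
               "noncoding")
  # position before the first complete codon of frame 2
  expect_equal(plasmavar:::pv_synonymy(ref, 2L, "A", 2L), "noncoding")
})

test_that("sample profiles count nonsynonymous+noncoding calls and genes", {
  mk_call <- function(gene, pos, syn) {
    tibble::tibble(amplicon_id = paste0("A_", gene), gene = gene,
                   position = pos, ref_base = "A", alt_base = "C",
                   frequency = 0.05, genomic_label = paste0(gene, ":", pos),
                   alias = NA_character_, known = FALSE, synonymy = syn)
  }
  calls <- dplyr::bind_rows(
    mk_call("TERT", 10, "noncoding"), mk_call("TERT", 20, "noncoding"),
    mk_call("TP53", 30, "nonsynonymous"), mk_call("TP53", 40, "nonsynonymous"),
    mk_call("TP53", 50, "synonymous"))
  prof <- pv_sample_profile(calls, 1.5)
  expect_equal(prof$n_mutations, 4L)
  expect_equal(prof$n_genes, 2L)

  empty <- pv_sample_profile(calls[0, ], 2)
  expect_equal(empty$n_mutations, 0L)
  expect_equal(empty$n_genes, 0L)

  # 37 calls over the five panel genes (16/9/6/4/2)
  sizes <- c(TERT = 16, TP53 = 9, AXIN1 = 6, ARID1A = 4, CTNNB1 = 2)
  many <- dplyr::bind_rows(lapply(names(sizes), function(g) {
    dplyr::bind_rows(lapply(seq_len(sizes[[g]]), function(i) {
      mk_call(g, i * 3, if (g == "TERT") "noncoding" else "nonsynonymous")
    }))
  }))
  prof37 <- pv_sample_profile(many, 1.99)
  expect_equal(prof37$n_mutations, 37L)
  expect_equal(prof37$n_genes, 5L)

  expect_error(pv_sample_profile(calls, -1), "non-negative")
})

test_that("variant tables export to minimal VCF", {
  panel <- toy_panel()
  tr <- trimmed_ref(panel)
  h1 <- tr; substr(h1, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                        substr(tr, 5, 5))[1]
  cons <- cons_tbl(panel, c(tr, h1), c(0.95, 0.05))
  calls <- pv_call_variants(cons, panel)
  path <- withr::local_tempfile(fileext = ".vcf")
  pv_write_vcf(calls, path, sample_id = "s1")
  lines <- readLines(path)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), nrow(calls))
  expect_match(body[1], "AF=0.05")
  expect_match(body[1], "GENE=TP53")
  expect_equal(length(strsplit(body[1], "\t")[[1]]), 8L)
})
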