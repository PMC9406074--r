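#' Specify variants to spike into simulated reads
#'
#' Helper constructor for the ground-truth table consumed by
#' [pv_simulate_reads()]. Each row is one single-nucleotide variant to spike:
#' a read pair from the allowed strand(s) carries the alternate allele with
#' probability `true_frequency`.
#'
#' @param panel Panel the variants refer to.
#' @param amplicon_id,position,alt_base,true_frequency,strands Vectors
#'   (recycled to a common length): target amplicon, 1-based position within
#'   its reference, alternate base, carriage probability in (0, 1), and
#'   `"both"`, `"forward_only"` or `"reverse_only"`.
#' @return A tibble with one row per variant, including the reference base.
#' @export
pv_variant_specs <- function(panel, amplicon_id, position, alt_base,
                             true_frequency, strands = "both") {
  specs <- tibble::tibble(amplicon_id = amplicon_id,
                          position = as.integer(position),
                          alt_base = alt_base,
                          true_frequency = true_frequency,
                          strands = strands)
  idx <- match(specs$amplicon_id, panel$amplicon_id)
  if (anyNA(idx)) {
    abort(paste("variant spec references unknown amplicon:",
                paste(unique(specs$amplicon_id[is.na(idx)]), collapse = ", ")))
  }
  L <- nchar(panel$reference_seq)[idx]
  bad <- specs$position < 1L | specs$position > L
  if (any(bad)) {
    b <- which(bad)[1]
    abort(sprintf("variant position %d outside reference of amplicon %s",
                  specs$position[b], specs$amplicon_id[b]))
  }
  specs$ref_base <- substr(panel$reference_seq[idx], specs$position,
                           specs$position)
  if (any(specs$ref_base == specs$alt_base))
    abort("alt_base must differ from the reference base")
  pv_check_dna(specs$alt_base, "alt_base")
  if (any(specs$true_frequency <= 0 | specs$true_frequency >= 1))
    abort("true_frequency must lie in (0, 1)")
  if (!all(specs$strands %in% c("both", "forward_only", "reverse_only")))
    abort("strands must be 'both', 'forward_only' or 'reverse_only'")
  specs[c("amplicon_id", "position", "ref_base", "alt_base",
          "true_frequency", "strands")]
}

#' Simulate paired-end amplicon reads with spiked-in variants
#'
#' Emulates single-amplicon PCR sequencing on a 2 x `read_length` paired-end
#' run: each read pair covers the full amplicon (read 1 from the forward
#' primer, read 2 from the reverse primer), so mates overlap by
#' `2 * read_length - amplicon_length` bases. Pairs are split ~50/50 between
#' sequencing orientations, substitution errors are applied independently per
#' base, and Phred scores are drawn from a truncated normal with an explicit
#' low-quality tail so the read-level Q30 filter has non-trivial work.
#' Indels are not simulated.
#'
#' @param panel Amplicon panel from [pv_make_panel()] / [pv_read_panel()].
#' @param variant_specs Optional tibble from [pv_variant_specs()].
#' @param read_length Read length in bases (default 150, i.e. 2 x 150 mode).
#' @param depth_per_amplicon Number of read pairs per amplicon.
#' @param substitution_error_rate Per-base substitution error probability.
#' @param quality_mean,quality_sd Mean and sd of the per-base Phred score
#'   before clipping to [2, 40].
#' @param low_q_prob Probability that a base's score is instead drawn
#'   uniformly from 10..(q-1) below Q30 (the low-quality tail).
#' @param seed Master seed; per-amplicon child streams keep the output stable
#'   under partial re-runs.
#' @param fastq_prefix If non-`NULL`, write `<prefix>_R1.fastq[.gz]`,
#'   `<prefix>_R2.fastq[.gz]` and `<prefix>_truth.tsv`.
#' @param gzip Compress FASTQ output.
#' @return A list with `reads` (tibble: `read_id`, `amplicon_id`,
#'   `true_strand`, `seq1`, `qual1`, `seq2`, `qual2`), `truth` (the variant
#'   specs plus realized post-sampling fractions; for strand-restricted
#'   variants the realized fraction is taken over pairs of the allowed
#'   strand(s)), and `files` (paths, or `NULL`).
#' @export
#' @examples
#' panel <- pv_make_panel(2, seed = 1)
#' specs <- pv_variant_specs(panel, panel$amplicon_id[1], 50, "A", 0.3)
#' sim <- pv_simulate_reads(panel, specs, depth_per_amplicon = 100, seed = 1)
#' sim$truth
pv_simulate_reads <- function(panel, variant_specs = NULL,
                              read_length = 150L,
                              depth_per_amplicon = 1000L,
                              substitution_error_rate = 0.001,
                              quality_mean = 37, quality_sd = 3,
                              low_q_prob = 0.01,
                              seed = 1L,
                              fastq_prefix = NULL, gzip = FALSE) {
  pv_validate_panel(panel)
  read_length <- as.integer(read_length)
  depth <- as.integer(depth_per_amplicon)
  L_all <- nchar(panel$reference_seq)
  if (any(2L * read_length - L_all < 20L)) {
    abort("2 * read_length must exceed every amplicon length by >= 20 (mates must overlap)")
  }
  if (!is.null(variant_specs) && nrow(variant_specs)) {
    variant_specs <- pv_variant_specs(panel, variant_specs$amplicon_id,
                                      variant_specs$position,
                                      variant_specs$alt_base,
                                      variant_specs$true_frequency,
                                      variant_specs$strands %||% "both")
  }

  all_reads <- vector("list", nrow(panel))
  truth_rows <- vector("list", nrow(panel))
  for (k in seq_len(nrow(panel))) {
    set.seed(pv_child_seed(seed, k))
    amp <- panel[k, ]
    L <- L_all[k]
    ref_chars <- strsplit(amp$reference_seq, "")[[1]]
    strand <- ifelse(runif(depth) < 0.5, "forward", "reverse")

    tmpl <- matrix(ref_chars, nrow = depth, ncol = L, byrow = TRUE)
    specs_k <- if (is.null(variant_specs)) NULL else
      variant_specs[variant_specs$amplicon_id == amp$amplicon_id, ]
    if (!is.null(specs_k) && nrow(specs_k)) {
      realized <- numeric(nrow(specs_k))
      eligible_n <- integer(nrow(specs_k))
      for (v in seq_len(nrow(specs_k))) {
        allowed <- switch(specs_k$strands[v],
                          both = rep(TRUE, depth),
                          forward_only = strand == "forward",
                          reverse_only = strand == "reverse")
        carrier <- allowed & (runif(depth) < specs_k$true_frequency[v])
        tmpl[carrier, specs_k$position[v]] <- specs_k$alt_base[v]
        eligible_n[v] <- sum(allowed)
        realized[v] <- if (eligible_n[v]) sum(carrier) / eligible_n[v] else NA_real_
      }
      truth_rows[[k]] <- dplyr::mutate(specs_k,
                                       n_pairs_eligible = eligible_n,
                                       realized_frequency = realized)
    }

    # Orient the template per pair: reverse-orientation pairs sequence the
    # reverse complement of the amplicon.
    is_rev <- strand == "reverse"
    if (any(is_rev)) {
      rc <- matrix(pv_complement_base(tmpl[is_rev, , drop = FALSE]),
                   nrow = sum(is_rev))[, L:1, drop = FALSE]
      tmpl[is_rev, ] <- rc
    }
    r1 <- tmpl[, seq_len(read_length), drop = FALSE]
    r2 <- tmpl[, seq(L - read_length + 1L, L), drop = FALSE]
    # read 2 as sequenced: reverse complement of the template's 3' end
    r2 <- matrix(pv_complement_base(r2), nrow = depth)[, read_length:1,
                                                       drop = FALSE]

    add_errors <- function(m) {
      if (substitution_error_rate <= 0) return(m)
      hit <- which(runif(length(m)) < substitution_error_rate)
      if (length(hit)) {
        cur <- m[hit]
        m[hit] <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1L),
                         character(1))
      }
      m
    }
    r1 <- add_errors(r1)
    r2 <- add_errors(r2)

    draw_qual <- function(n_bases) {
      q <- as.integer(pmin(40L, pmax(2L, round(rnorm(n_bases, quality_mean,
                                                     quality_sd)))))
      low <- runif(n_bases) < low_q_prob
      if (any(low)) q[low] <- sample(10:29, sum(low), replace = TRUE)
      q
    }
    q1 <- matrix(draw_qual(depth * read_length), nrow = depth)
    q2 <- matrix(draw_qual(depth * read_length), nrow = depth)

    all_reads[[k]] <- tibble::tibble(
      read_id = sprintf("%s:%06d", amp$amplicon_id, seq_len(depth)),
      amplicon_id = amp$amplicon_id,
      true_strand = strand,
      seq1 = pv_paste_rows(r1),
      qual1 = pv_phred_encode_rows(q1),
      seq2 = pv_paste_rows(r2),
      qual2 = pv_phred_encode_rows(q2)
    )
  }

  reads <- dplyr::bind_rows(all_reads)
  truth <- dplyr::bind_rows(truth_rows)
  files <- NULL
  if (!is.null(fastq_prefix)) {
    files <- pv_write_fastq_pair(reads, fastq_prefix, gzip = gzip)
    truth_path <- paste0(fastq_prefix, "_truth.tsv")
    write.table(as.data.frame(truth), truth_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    files <- c(files, truth = truth_path)
  }
  list(reads = reads, truth = truth, files = files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a pair of FASTQ files
#'
#' Four-line FASTQ records with Phred+33 qualities; mate files are suffixed
#' `_R1` / `_R2`.
#'
#' @param reads Tibble with `read_id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @param prefix Output path prefix.
#' @param gzip Write gzip-compressed files.
#' @return `pv_write_fastq_pair()` returns the two paths (named `r1`, `r2`);
#'   `pv_read_fastq_pair()` returns the reads tibble.
#' @export
pv_write_fastq_pair <- function(reads, prefix, gzip = FALSE) {
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  p1 <- paste0(prefix, "_R1", ext)
  p2 <- paste0(prefix, "_R2", ext)
  wr <- function(path, ids, seqs, quals) {
    con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    rec <- as.vector(rbind(paste0("@", ids), seqs, "+", quals))
    writeLines(rec, con)
  }
  wr(p1, reads$read_id, reads$seq1, reads$qual1)
  wr(p2, reads$read_id, reads$seq2, reads$qual2)
  c(r1 = p1, r2 = p2)
}

#' @rdname pv_write_fastq_pair
#' @param r1,r2 Paths to the two mate FASTQ files (optionally gzipped).
#' @export
pv_read_fastq_pair <- function(r1, r2) {
  rd <- function(path) {
    x <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fastq",
                                   with.qualities = TRUE),
      error = function(e) abort(sprintf("malformed FASTQ '%s': %s", path,
                                        conditionMessage(e))))
    tibble::tibble(read_id = sub("\\s.*$", "", names(x)),
                   seq = unname(as.character(x)),
                   qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
  }
  a <- rd(r1)
  b <- rd(r2)
  if (nrow(a) != nrow(b) || !identical(a$read_id, b$read_id)) {
    abort("R1 and R2 read ids do not line up")
  }
  tibble::tibble(read_id = a$read_id, seq1 = a$seq, qual1 = a$qual,
                 seq2 = b$seq, qual2 = b$qual)
}
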