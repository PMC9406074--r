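# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Exhaustive overlap-merge oracle: scan every candidate overlap length,
# score by the same published rule (>= min_overlap bases, mismatch fraction
# <= max_frac, N mismatches, longest qualifying wins; conflicts to the
# higher-quality base, tie to read 1).
oracle_merge <- function(s1, q1, s2_raw, q2_raw, min_overlap = 20,
                         max_frac = 0.10) {
  s2 <- oracle_revcomp(s2_raw)
  q2 <- paste(rev(strsplit(q2_raw, "")[[1]]), collapse = "")
  a1 <- strsplit(s1, "")[[1]]; a2 <- strsplit(s2, "")[[1]]
  b1 <- utf8ToInt(q1) - 33L;   b2 <- utf8ToInt(q2) - 33L
  l1 <- length(a1); l2 <- length(a2)
  if (min(l1, l2) < min_overlap) return(NULL)
  best <- NULL
  for (o in seq(min(l1, l2), min_overlap)) {
    x <- a1[(l1 - o + 1):l1]; y <- a2[1:o]
    mism <- sum(x != y | x == "N" | y == "N")
    if (mism / o <= max_frac + 1e-12) {
      qx <- b1[(l1 - o + 1):l1]; qy <- b2[1:o]
      ov_base <- ifelse(qy > qx, y, x)
      ov_q <- pmax(qx, qy)
      best <- list(
        seq = paste(c(a1[seq_len(l1 - o)], ov_base, a2[seq(o + 1, length.out = l2 - o)]),
                    collapse = ""),
        qual = intToUtf8(c(b1[seq_len(l1 - o)], ov_q,
                           b2[seq(o + 1, length.out = l2 - o)]) + 33L),
        overlap_len = o, overlap_mismatches = mism)
      break
    }
  }
  best
}

# Pair-counting Mann-Whitney oracle: U = #(a > b) + 0.5 #(a = b).
oracle_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# Pair-counting AUC oracle: P(pos > neg) + 0.5 P(pos = neg).
oracle_auc <- function(pos, neg) oracle_u(pos, neg) / (length(pos) * length(neg))

# Hand log-rank oracle for two groups: sum of hypergeometric contributions
# at each distinct event time (chi-square form, group 1 as reference).
oracle_logrank <- function(time, event, group) {
  g <- as.integer(as.factor(group)) - 1L  # 0 / 1
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1L)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == 1L)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# Per-read allele counting oracle: frequency of (position, alt) among reads
# that belong to the retained consensus haplotypes.
oracle_variant_freqs <- function(read_seqs, retained_seqs, ref) {
  keep <- read_seqs[read_seqs %in% retained_seqs]
  ref_chars <- strsplit(ref, "")[[1]]
  out <- list()
  for (s in unique(keep)) {
    cc <- strsplit(s, "")[[1]]
    for (pos in which(cc != ref_chars)) {
      key <- paste0(pos, ":", cc[pos])
      out[[key]] <- (out[[key]] %||% 0) + sum(keep == s)
    }
  }
  if (!length(out)) return(tibble::tibble(position = integer(0),
                                          alt = character(0),
                                          frequency = numeric(0)))
  tibble::tibble(
    position = as.integer(sub(":.*", "", names(out))),
    alt = sub(".*:", "", names(out)),
    frequency = as.numeric(unlist(out)) / length(keep))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared fixture: a small panel plus clean simulated reads.
make_clean_sim <- function(n_amp = 3, depth = 300, seed = 11,
                           specs = NULL, error = 0) {
  panel <- pv_make_panel(n_amp, seed = seed)
  sim <- pv_simulate_reads(panel, specs, depth_per_amplicon = depth,
                           substitution_error_rate = error,
                           low_q_prob = 0, seed = seed + 1)
  list(panel = panel, sim = sim)
}

# Build a merged-read tibble directly (bypassing the merger) so quality and
# demux stages can be tested on constructed inputs.
fake_merged <- function(seq, qual, read_id = sprintf("r%03d", seq_along(seq))) {
  tibble::tibble(read_id = read_id, seq = seq, qual = qual,
                 merged = TRUE, overlap_len = NA_integer_,
                 overlap_mismatches = NA_integer_)
}

qual_string <- function(q, n) strrep(intToUtf8(q + 33L), n)
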