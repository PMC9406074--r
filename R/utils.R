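# Internal sequence/quality helpers. DNA strings are plain uppercase
# character vectors over {A,C,G,T,N}; qualities are Phred+33 strings.

DNA_BASES <- c("A", "C", "G", "T")

pv_revcomp <- function(x) {
  out <- character(length(x))
  nz <- !is.na(x) & nzchar(x)
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out[!nz] <- x[!nz]
  out
}

pv_reverse_str <- function(x) {
  out <- character(length(x))
  nz <- !is.na(x) & nzchar(x)
  if (any(nz)) {
    out[nz] <- as.character(Biostrings::reverse(Biostrings::BStringSet(x[nz])))
  }
  out[!nz] <- x[!nz]
  out
}

pv_complement_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[b])
}

# Phred+33 encode a matrix/vector of integer scores (row-major per read).
pv_phred_encode_rows <- function(qmat) {
  stopifnot(is.matrix(qmat))
  L <- ncol(qmat)
  big <- rawToChar(as.raw(as.vector(t(qmat)) + 33L))
  starts <- seq(1L, by = L, length.out = nrow(qmat))
  substring(big, starts, starts + L - 1L)
}

pv_phred_decode <- function(q) utf8ToInt(q) - 33L

# Collapse a character matrix of single bases to one string per row.
pv_paste_rows <- function(m) {
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

pv_check_dna <- function(x, what = "sequence", allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside {A,C,G,T%s} (first offender: %s)",
                  what, if (allow_n) ",N" else "", x[which(bad)[1]]))
  }
  invisible(x)
}

# Derive a 32-bit child seed from a master seed and a stream index, so
# per-amplicon / per-patient streams are stable under partial re-runs.
pv_child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 16807) %% 2147483647)
}

pv_hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
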