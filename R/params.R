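#' Read-processing parameters
#'
#' Bundles the thresholds applied while merging read pairs, filtering merged
#' reads on quality, and demultiplexing by primer. The defaults are the
#' standard settings for haplotype-based deep amplicon sequencing of plasma
#' cfDNA: at least 20 overlapping bases with at most 10% differences for the
#' merge, discarding of full reads with 5% or more bases below Q30, and
#' primer demultiplexing tolerating at most three differences per primer.
#'
#' @param min_overlap Minimum number of overlapping bases required to merge a
#'   read pair.
#' @param max_mismatch_frac Maximum fraction of disagreeing bases tolerated
#'   within the overlap (a fraction exactly at the threshold still merges).
#' @param q_threshold Phred score below which a base counts as low quality.
#' @param max_low_q_frac A merged read whose fraction of bases below
#'   `q_threshold` is greater than or equal to this value is discarded.
#' @param max_primer_diff Maximum mismatches tolerated against each primer
#'   during demultiplexing.
#' @return A list of class `pv_pipeline_params`.
#' @export
#' @examples
#' pv_pipeline_params()
pv_pipeline_params <- function(min_overlap = 20L,
                               max_mismatch_frac = 0.10,
                               q_threshold = 30L,
                               max_low_q_frac = 0.05,
                               max_primer_diff = 3L) {
  p <- list(min_overlap = as.integer(min_overlap),
            max_mismatch_frac = max_mismatch_frac,
            q_threshold = as.integer(q_threshold),
            max_low_q_frac = max_low_q_frac,
            max_primer_diff = as.integer(max_primer_diff))
  if (p$min_overlap < 1L) abort("min_overlap must be >= 1")
  if (p$max_mismatch_frac < 0 || p$max_mismatch_frac > 1)
    abort("max_mismatch_frac must be in [0, 1]")
  if (p$q_threshold < 0L) abort("q_threshold must be >= 0")
  if (p$max_low_q_frac < 0 || p$max_low_q_frac > 1)
    abort("max_low_q_frac must be in [0, 1]")
  if (p$max_primer_diff < 0L) abort("max_primer_diff must be >= 0")
  structure(p, class = "pv_pipeline_params")
}

#' Haplotype and variant abundance thresholds
#'
#' Haplotypes below `min_hap_abundance` on either strand (or absent from one
#' strand altogether) are discarded before variant calling; variants whose
#' aggregate frequency is below `min_variant_freq` are dropped. Both
#' thresholds are strict: an abundance exactly at the threshold survives.
#'
#' @param min_hap_abundance Per-strand haplotype abundance floor
#'   (default 0.001, i.e. 0.1%).
#' @param min_variant_freq Aggregate variant frequency floor
#'   (default 0.01, i.e. 1%).
#' @return A list of class `pv_filter_params`.
#' @export
pv_filter_params <- function(min_hap_abundance = 0.001,
                             min_variant_freq = 0.01) {
  if (!(min_hap_abundance > 0 && min_hap_abundance < min_variant_freq &&
        min_variant_freq <= 1)) {
    abort("need 0 < min_hap_abundance < min_variant_freq <= 1")
  }
  structure(list(min_hap_abundance = min_hap_abundance,
                 min_variant_freq = min_variant_freq),
            class = "pv_filter_params")
}
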