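#' Apply the PE Bias Detector
#'
#' Imbalanced paired-end chemistries (e.g. 50/35-base SOLiD pairs) produce a
#' short mate that is disproportionately artefact-prone.  This filter bins a
#' called variant when, in the test sample's own alignment file, the
#' alternate allele is supported by at least one read but *only* by
#' short-mate reads (zero long-mate support).  Variants with no observed
#' alternate support at all are not "evident only in short reads": they are
#' kept and flagged `FAVR_PE=no_support_observed` for audit.  The filter is
#' the identity on balanced chemistries, where no read is classified
#' short-mate under the default by-length rule.  Only the test sample's BAM
#' is consulted.
#'
#' @param variants A [snv_calls()] data frame.
#' @param test_bam The test sample's indexed BAM file.
#' @param mate_config A [mate_class_config()].
#' @param gates A [quality_gates()].
#' @param evidence Optional precomputed [collect_pileup_evidence()] result
#'   for `variants` against `test_bam` (must use the same `mate_config`).
#' @return A `favr_outcome`.
#' @export
apply_pe_bias_filter <- function(variants, test_bam,
                                 mate_config = mate_class_config(),
                                 gates = quality_gates(), evidence = NULL) {
  variants <- as_snv_calls(variants)
  if (is.null(evidence))
    evidence <- collect_pileup_evidence(test_bam, variants, gates = gates,
                                        mate_config = mate_config)
  stopifnot(nrow(evidence) == nrow(variants))
  binned_flag <- evidence$alt_count >= 1L &
    evidence$alt_count_long_mate == 0L
  no_support <- evidence$alt_count == 0L

  kept <- variants[!binned_flag, , drop = FALSE]
  if (nrow(kept)) {
    flag_no <- no_support[!binned_flag]
    kept$info[flag_no] <- info_add(kept$info[flag_no], "FAVR_PE",
                                   "no_support_observed")
  }
  binned <- variants[binned_flag, , drop = FALSE]
  if (nrow(binned))
    binned$info <- info_add(binned$info, "FAVR_BIN", "short_mate_only")
  prov <- data.frame(key = variant_key(variants),
                     alt_count = evidence$alt_count,
                     alt_count_long_mate = evidence$alt_count_long_mate,
                     alt_count_short_mate = evidence$alt_count_short_mate,
                     depth = evidence$depth,
                     decision = ifelse(binned_flag, "binned", "kept"),
                     reason = ifelse(binned_flag, "short_mate_only",
                                     ifelse(no_support, "no_support_observed",
                                            "")),
                     stringsAsFactors = FALSE)
  favr_outcome(restore_snv(kept, variants), restore_snv(binned, variants),
               prov, tool = "pe-bias",
               params = list(mode = mate_config$mode,
                             length_cutoff = mate_config$length_cutoff %||%
                               "longest-at-locus",
                             short_mate_ordinal = mate_config$short_mate_ordinal),
               files = test_bam)
}
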