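#' Configuration for the Rare and True Filter
#'
#' The filter has two parameters.  `read_threshold` is the number of reads in
#' a comparator that must carry the same base at the same position for that
#' comparator to be considered *variant-like* (the count is compared with
#' `>=`).  `percent_threshold` is the percentage of comparator alignment
#' files that may be variant-like before the variant is discarded; a variant
#' is kept only while the variant-like percentage stays *below* this
#' threshold.  The reference study setting is `read_threshold = 1`,
#' `percent_threshold = 30` with a panel of 8 comparator BAM files drawn from
#' the same chemistry and processing pipeline, excluding the test sample and
#' its relatives.
#'
#' @param comparators Named character vector of comparator BAM paths (names
#'   are sample ids; unnamed entries take their file name).  Length >= 1,
#'   unique ids.
#' @param read_threshold Integer >= 1; alt reads needed for a comparator to
#'   be variant-like.
#' @param percent_threshold Percentage in (0, 100].
#' @param gates A [quality_gates()] object.
#' @param test_sample Optional test-sample id; a warning is raised if it also
#'   appears in the comparator panel (keeping relatives and the test sample
#'   out of the panel is the caller's responsibility).
#' @return A `favr_filter_config` list.
#' @export
filter_config <- function(comparators, read_threshold = 1L,
                          percent_threshold = 30, gates = quality_gates(),
                          test_sample = NULL) {
  comparators <- normalise_panel(comparators)
  read_threshold <- as.integer(read_threshold)
  stopifnot(read_threshold >= 1L,
            percent_threshold > 0, percent_threshold <= 100)
  if (!is.null(test_sample) && test_sample %in% names(comparators))
    warning("test sample '", test_sample,
            "' appears in the comparator panel", call. = FALSE)
  structure(list(comparators = comparators,
                 read_threshold = read_threshold,
                 percent_threshold = percent_threshold,
                 gates = gates, test_sample = test_sample),
            class = "favr_filter_config")
}

#' Is a sample variant-like at a locus?
#'
#' A sample is variant-like when its count of reads carrying the alternate
#' base at the position is greater than or equal to the read threshold.
#'
#' @param alt_count Alt-supporting read count(s), or a data frame with an
#'   `alt_count` column as returned by [collect_pileup_evidence()].
#' @param read_threshold Integer >= 1.
#' @return Logical vector.
#' @examples
#' is_variant_like(1, read_threshold = 1)  # TRUE
#' is_variant_like(1, read_threshold = 2)  # FALSE
#' @export
is_variant_like <- function(alt_count, read_threshold = 1L) {
  if (is.data.frame(alt_count)) alt_count <- alt_count$alt_count
  stopifnot(read_threshold >= 1L)
  alt_count >= read_threshold
}

#' Percentage of comparator files that are variant-like
#'
#' The denominator is the full panel size: a comparator with no coverage at
#' the locus still counts in the denominator (it simply cannot be
#' variant-like).  See [apply_rare_and_true()] for the covered-only
#' alternative.
#'
#' @param alt_counts Integer vector (or matrix, loci x comparators) of
#'   alt-supporting read counts, one per panel member.
#' @param read_threshold Integer >= 1.
#' @param panel_size Denominator; defaults to the number of counts supplied.
#' @return Percentage(s) in `[0, 100]`.
#' @examples
#' comparator_percent(c(1, 2, 0, 0, 0, 0, 0, 0))  # 25
#' @export
comparator_percent <- function(alt_counts, read_threshold = 1L,
                               panel_size = NULL) {
  if (is.matrix(alt_counts)) {
    panel_size <- panel_size %||% ncol(alt_counts)
    if (panel_size < 1L) stop("empty comparator panel", call. = FALSE)
    return(100 * rowSums(alt_counts >= read_threshold) / panel_size)
  }
  panel_size <- panel_size %||% length(alt_counts)
  if (panel_size < 1L) stop("empty comparator panel", call. = FALSE)
  100 * sum(is_variant_like(alt_counts, read_threshold)) / panel_size
}

#' Apply the Rare and True Filter
#'
#' For every candidate variant, counts how many comparator alignment files
#' are variant-like at the site and discards (bins) the variant when the
#' variant-like percentage reaches the percent threshold.  Variants are kept
#' while the percentage is strictly below the threshold — the boundary case
#' is discarded.  The threshold comparison is done on integers
#' (`n_variant_like * 100 >= percent * panel_size`) so floating-point
#' rounding cannot flip boundary cases.
#'
#' @param variants A [snv_calls()] data frame.
#' @param config A [filter_config()].
#' @param evidence Optional precomputed panel evidence from
#'   [collect_panel_evidence()] (rows aligned with `variants`); when `NULL`
#'   it is collected from the comparator BAMs.
#' @param covered_only If `TRUE`, the percentage denominator is the number of
#'   comparators with nonzero qualifying depth at the locus rather than the
#'   full panel (stricter at poorly covered sites; a variant with zero
#'   covered comparators is kept).  Default `FALSE`.
#' @return A `favr_outcome`; `$provenance` records, per variant, each
#'   comparator's `alt_count/depth`, the variant-like count and percentage,
#'   and the decision.
#' @examples
#' # With the study settings (t = 1, 30%, 8 comparators), alt reads in 2
#' # comparators give 25% (< 30, kept) and in 3 comparators 37.5% (binned).
#' @export
apply_rare_and_true <- function(variants, config, evidence = NULL,
                                covered_only = FALSE) {
  stopifnot(inherits(config, "favr_filter_config"))
  variants <- as_snv_calls(variants)
  panel <- config$comparators
  npanel <- length(panel)
  if (is.null(evidence))
    evidence <- collect_panel_evidence(variants, panel, gates = config$gates)
  stopifnot(length(evidence) == npanel,
            all(vapply(evidence, nrow, 0L) == nrow(variants)))

  n <- nrow(variants)
  alt_mat <- do.call(cbind, c(lapply(evidence, function(e) e$alt_count),
                              list(matrix(integer(), n, 0))))
  dep_mat <- do.call(cbind, c(lapply(evidence, function(e) e$depth),
                              list(matrix(integer(), n, 0))))
  like <- alt_mat >= config$read_threshold
  n_like <- if (n) rowSums(like) else integer(0)
  denom <- if (covered_only) {
    if (n) rowSums(dep_mat > 0L) else integer(0)
  } else rep(npanel, n)
  pct <- ifelse(denom > 0L, 100 * n_like / denom, 0)
  # integer-exact boundary: binned iff n_like * 100 >= p * denom
  binned_flag <- denom > 0L &
    (n_like * 100 >= config$percent_threshold * denom)

  kept <- variants[!binned_flag, , drop = FALSE]
  binned <- variants[binned_flag, , drop = FALSE]
  if (nrow(binned)) {
    binned$info <- info_add(binned$info, "FAVR_BIN", "comparator_signature")
    binned$info <- info_add(binned$info, "FAVR_CMP_PCT",
                            format(pct[binned_flag], trim = TRUE))
  }
  detail <- if (n) {
    apply(matrix(paste0(rep(names(panel), each = n), ":", alt_mat, "/",
                        dep_mat), n, npanel), 1, paste, collapse = ",")
  } else character(0)
  prov <- data.frame(key = variant_key(variants),
                     comparator_counts = detail,
                     n_variant_like = as.integer(n_like),
                     panel_size = as.integer(denom),
                     percent_variant_like = pct,
                     decision = ifelse(binned_flag, "binned", "kept"),
                     reason = ifelse(binned_flag, "comparator_signature", ""),
                     stringsAsFactors = FALSE)
  favr_outcome(restore_snv(kept, variants), restore_snv(binned, variants),
               prov, tool = "rare-and-true",
               params = list(read_threshold = config$read_threshold,
                             percent_threshold = config$percent_threshold,
                             panel_size = npanel,
                             covered_only = covered_only),
               files = unname(panel))
}
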