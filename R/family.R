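#' Annotate variants with read-level evidence from relatives
#'
#' For each variant and each relative's alignment file, records the
#' alt-supporting read count and depth, and flags the relative as sharing the
#' variant when the alt count reaches `read_threshold` (default 1: evidence
#' in *any* read counts, which catches variants a genotype caller missed in
#' the relative through rigid thresholds).  Annotation never adds or removes
#' variants; it only writes the `FAVR_FAM` (per-relative `sample:alt/depth`
#' entries, in lexicographic sample-id order) and `FAVR_FAM_N` (number of
#' relatives with evidence) INFO keys.  Re-annotating overwrites these keys
#' rather than duplicating them.
#'
#' @param variants A [snv_calls()] data frame.
#' @param relatives Named character vector of relatives' BAM paths (names are
#'   sample ids).
#' @param read_threshold Integer >= 1; alt reads needed to flag a relative as
#'   sharing the variant.
#' @param gates A [quality_gates()].
#' @return The input variants (same rows, same order) with updated `info`;
#'   the per-relative evidence table is attached as attribute
#'   `"family_annotation"` (columns `key`, `sample_id`, `alt_count`, `depth`,
#'   `shared`).
#' @export
annotate_family <- function(variants, relatives, read_threshold = 1L,
                            gates = quality_gates()) {
  variants <- as_snv_calls(variants)
  relatives <- normalise_panel(relatives)
  relatives <- relatives[order(names(relatives))]
  read_threshold <- as.integer(read_threshold)
  stopifnot(read_threshold >= 1L)
  evidence <- collect_panel_evidence(variants, relatives, gates = gates)
  n <- nrow(variants)

  ann <- do.call(rbind, lapply(names(relatives), function(id) {
    e <- evidence[[id]]
    data.frame(key = variant_key(variants), sample_id = id,
               alt_count = e$alt_count, depth = e$depth,
               shared = e$alt_count >= read_threshold,
               stringsAsFactors = FALSE)
  }))
  if (n > 0L) {
    entries <- vapply(seq_len(n), function(i) {
      paste(vapply(names(relatives), function(id) {
        e <- evidence[[id]]
        paste0(id, ":", e$alt_count[i], "/", e$depth[i])
      }, ""), collapse = ",")
    }, "")
    n_shared <- Reduce(`+`, lapply(names(relatives), function(id)
      as.integer(evidence[[id]]$alt_count >= read_threshold)))
    info <- info_drop(variants$info, c("FAVR_FAM", "FAVR_FAM_N"))
    info <- info_add(info, "FAVR_FAM", entries)
    info <- info_add(info, "FAVR_FAM_N", as.integer(n_shared))
    variants$info <- info
  }
  attr(variants, "family_annotation") <- ann
  variants
}
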