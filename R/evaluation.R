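#' Shared variant identities between two variant lists
#'
#' Two candidate variants are the same variant only under exact
#' (chrom, pos, ref, alt) identity — the same position with different
#' alternate alleles is not shared.
#'
#' @param variants_a,variants_b [snv_calls()] data frames.
#' @return Character vector of shared `chrom:pos:ref:alt` keys.
#' @export
shared_snvs <- function(variants_a, variants_b) {
  intersect(variant_key(as_snv_calls(variants_a)),
            variant_key(as_snv_calls(variants_b)))
}

#' Observed versus expected shared variants between relatives
#'
#' First cousins share on average 12.5% of their DNA, so if two cousins'
#' candidate lists contain only genuine rare variants the number of shared
#' variants should be close to the kinship coefficient times their (mean)
#' variant count.  Recurrent artefacts and common variants are shared at far
#' higher rates, so an observed/expected (O/E) ratio well above 1 before
#' filtering, falling to about 1 after filtering, indicates that filtering
#' removed predominantly non-rare or artefactual signal.
#'
#' @param n_a,n_b Variant counts for the two relatives.
#' @param observed_shared Number of variants with identical
#'   (chrom, pos, ref, alt) in both lists.
#' @param kinship Expected shared fraction of DNA (default 0.125 for first
#'   cousins).
#' @param aggregate How to combine `n_a` and `n_b` into the expectation
#'   baseline: `"mean"` (default), `"min"` or `"max"`.
#' @return A `favr_oe` list with fields `n_a`, `n_b`, `observed_shared`,
#'   `kinship`, `expected_shared` and `oe_ratio`.
#' @examples
#' observed_expected(100, 100, 25)  # expected 12.5, O/E 2
#' @export
observed_expected <- function(n_a, n_b, observed_shared, kinship = 0.125,
                              aggregate = c("mean", "min", "max")) {
  aggregate <- match.arg(aggregate)
  stopifnot(n_a >= 0, n_b >= 0, observed_shared >= 0,
            kinship > 0, kinship <= 1)
  if (observed_shared > min(n_a, n_b))
    stop("observed_shared cannot exceed min(n_a, n_b)", call. = FALSE)
  base <- switch(aggregate, mean = (n_a + n_b) / 2, min = min(n_a, n_b),
                 max = max(n_a, n_b))
  expected <- kinship * base
  if (expected == 0)
    stop("expected shared count is zero; O/E ratio undefined", call. = FALSE)
  structure(list(n_a = n_a, n_b = n_b, observed_shared = observed_shared,
                 kinship = kinship, aggregate = aggregate,
                 expected_shared = expected,
                 oe_ratio = observed_shared / expected),
            class = "favr_oe")
}

#' @export
print.favr_oe <- function(x, ...) {
  cat("<favr_oe> observed/expected shared variants\n")
  cat(sprintf("  n_a=%d n_b=%d observed=%d kinship=%.3f (%s)\n",
              x$n_a, x$n_b, x$observed_shared, x$kinship, x$aggregate))
  cat(sprintf("  expected=%.2f  O/E=%.3f\n", x$expected_shared, x$oe_ratio))
  invisible(x)
}

#' Project the sensitivity of comparator-signature filtering on known SNVs
#'
#' Assesses whether filtering on comparator signatures would discard genuine
#' variants, using a panel of known SNVs.  For each known SNV, any alignment
#' file showing the alternate allele at a read frequency of at least
#' `carrier_freq` percent (among files with qualifying depth) is judged a
#' *true carrier* and excluded.  If the alternate allele is then apparent in
#' any read in at least `artefact_fraction` percent of the remaining files,
#' the variant would have been judged an artefact — a projected
#' false-negative call.  The aggregate retained fraction is
#' `1 - projected_false_negatives / assessed`.
#'
#' @param known_snvs A [snv_calls()] data frame of known variant sites.
#' @param panel Named character vector of indexed BAM paths (>= 2 files).
#' @param carrier_freq Carrier read-frequency cutoff, percent (default 9).
#' @param artefact_fraction Artefact judgement cutoff on the fraction of
#'   remaining files with any alt read, percent (default 30).
#' @param gates A [quality_gates()].
#' @param zero_depth_in_remaining Count files with zero depth at the site in
#'   the remaining-file denominator (default `TRUE`).
#' @return A `favr_sensitivity` list: `$per_variant` data frame and
#'   `$aggregate` (fields `n_assessed`, `n_projected_false_negative`,
#'   `retained_fraction`).  SNVs covered in no file are excluded from the
#'   aggregate with a warning.
#' @export
sensitivity_projection <- function(known_snvs, panel, carrier_freq = 9,
                                   artefact_fraction = 30,
                                   gates = quality_gates(),
                                   zero_depth_in_remaining = TRUE) {
  known_snvs <- as_snv_calls(known_snvs)
  panel <- normalise_panel(panel)
  if (length(panel) < 2L)
    stop("sensitivity projection needs a panel of at least 2 alignment files",
         call. = FALSE)
  stopifnot(carrier_freq > 0, carrier_freq <= 100,
            artefact_fraction > 0, artefact_fraction <= 100)
  evidence <- collect_panel_evidence(known_snvs, panel, gates = gates)
  n <- nrow(known_snvs)
  alt_mat <- do.call(cbind, lapply(evidence, function(e) e$alt_count))
  dep_mat <- do.call(cbind, lapply(evidence, function(e) e$depth))
  if (n == 1L) { alt_mat <- matrix(alt_mat, 1L); dep_mat <- matrix(dep_mat, 1L) }

  per <- data.frame(key = variant_key(known_snvs),
                    n_carriers = integer(n), n_remaining = integer(n),
                    n_with_evidence = integer(n),
                    evidence_percent = numeric(n),
                    projected_false_negative = logical(n),
                    assessed = logical(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    dep <- dep_mat[i, ]; altc <- alt_mat[i, ]
    if (all(dep == 0L)) next  # uncovered everywhere: cannot be assessed
    carrier <- dep > 0L & (100 * altc >= carrier_freq * dep)
    remaining <- !carrier & (zero_depth_in_remaining | dep > 0L)
    per$n_carriers[i] <- sum(carrier)
    per$n_remaining[i] <- sum(remaining)
    if (sum(remaining) == 0L) next  # nothing left to judge against
    ev <- sum(altc[remaining] >= 1L)
    pct <- 100 * ev / sum(remaining)
    per$n_with_evidence[i] <- ev
    per$evidence_percent[i] <- pct
    per$projected_false_negative[i] <- ev * 100 >= artefact_fraction * sum(remaining)
    per$assessed[i] <- TRUE
  }
  skipped <- sum(!per$assessed)
  if (skipped > 0L)
    warning(skipped, " known SNV(s) skipped: no coverage or no remaining ",
            "files after carrier exclusion", call. = FALSE)
  n_assessed <- sum(per$assessed)
  n_fn <- sum(per$projected_false_negative[per$assessed])
  structure(list(
    per_variant = per,
    aggregate = list(
      n_assessed = n_assessed,
      n_projected_false_negative = n_fn,
      retained_fraction = if (n_assessed > 0L) 1 - n_fn / n_assessed
                          else NA_real_),
    params = list(carrier_freq = carrier_freq,
                  artefact_fraction = artefact_fraction,
                  panel_size = length(panel))),
    class = "favr_sensitivity")
}

#' @export
print.favr_sensitivity <- function(x, ...) {
  a <- x$aggregate
  cat("<favr_sensitivity> known-variant retention projection\n")
  cat(sprintf("  assessed: %d of %d SNVs (panel of %d files)\n",
              a$n_assessed, nrow(x$per_variant), x$params$panel_size))
  cat(sprintf("  projected false negatives: %d\n",
              a$n_projected_false_negative))
  if (!is.na(a$retained_fraction))
    cat(sprintf("  retained: %d/%d (%.1f%%)\n",
                a$n_assessed - a$n_projected_false_negative, a$n_assessed,
                100 * a$retained_fraction))
  invisible(x)
}
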