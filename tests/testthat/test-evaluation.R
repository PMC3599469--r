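test_that("shared variants require exact allele identity", {
  a <- snv_calls("chr1", c(10L, 20L, 30L), ref = c("A", "C", "G"),
                 alt = c("C", "T", "A"))
  expect_length(shared_snvs(a, a), 3L)
  b <- snv_calls("chr2", c(10L, 20L, 30L), ref = c("A", "C", "G"),
                 alt = c("C", "T", "A"))
  expect_length(shared_snvs(a, b), 0L)
  # same locus, different alternate allele: not shared
  c1 <- snv_calls("chr1", 10L, ref = "A", alt = "C")
  c2 <- snv_calls("chr1", 10L, ref = "A", alt = "T")
  expect_length(shared_snvs(c1, c2), 0L)
})

test_that("observed/expected arithmetic follows the kinship assumption", {
  oe <- observed_expected(100, 100, 25)
  expect_equal(oe$expected_shared, 12.5)
  expect_equal(oe$oe_ratio, 2)
  expect_equal(observed_expected(100, 100, 0)$oe_ratio, 0)
  expect_error(observed_expected(0, 0, 0), "zero")
  expect_error(observed_expected(10, 10, 11), "exceed")
  # unequal counts average into the baseline
  oe2 <- observed_expected(80, 120, 25)
  expect_equal(oe2$expected_shared, 12.5)
  # alternative aggregations
  expect_equal(observed_expected(80, 120, 10, aggregate = "min")$expected_shared,
               10)
  expect_equal(observed_expected(80, 120, 10, aggregate = "max")$expected_shared,
               15)
})

test_that("O/E is invariant under common scaling of counts", {
  base <- observed_expected(200, 160, 30)
  for (k in c(2, 5, 10)) {
    scaled <- observed_expected(200 * k, 160 * k, 30 * k)
    expect_equal(scaled$oe_ratio, base$oe_ratio)
  }
})

# Sensitivity panel: common variants are carried at heterozygous fractions
# (true carriers, to be excluded) and low-frequency mapping artefacts sit
# below the 9% carrier rule (so their recurrence projects false negatives).
cohort_sens_small <- function() get_fixture("coh_sens_small", function() {
  simulate_cohort(
    simulation_config(seed = 5, n_samples = 10, reference_length = 9000,
                      mean_coverage = 25, n_true_rare = 0, n_common = 6,
                      n_artefact_mapping = 6,
                      artefact_fraction = c(0.02, 0.04),
                      artefact_prevalence = c(0.6, 0.9)),
    file.path(tempdir(), "coh_sens_small"))
})

test_that("carriers are excluded and recurrent low-level signal projects false negatives", {
  co <- cohort_sens_small()
  known <- snv_calls(chrom = co$sites$chrom, pos = co$sites$pos,
                     ref = co$sites$ref, alt = co$sites$alt,
                     id = co$sites$site_id)
  panel <- stats::setNames(co$samples$bam, co$samples$sample_id)
  rep <- sensitivity_projection(known, panel)
  per <- rep$per_variant
  cls <- co$sites$class
  # heterozygous carriers (~50% alt) all hit the 9% rule
  expect_equal(per$n_carriers[cls == "common"],
               co$sites$n_carriers[cls == "common"])
  # with carriers gone no remaining file shows the allele: retained
  expect_false(any(per$projected_false_negative[cls == "common"]))
  # low-frequency artefacts are not carriers, so their recurrence in the
  # remaining files projects a false-negative call
  expect_true(all(per$projected_false_negative[cls == "artefact_mapping"]))
  expect_equal(rep$aggregate$n_assessed, nrow(co$sites))
  expect_equal(rep$aggregate$retained_fraction,
               1 - sum(cls == "artefact_mapping") / nrow(co$sites))
})

test_that("unassessable known SNVs are skipped with a warning", {
  co <- cohort_sens_small()
  panel <- stats::setNames(co$samples$bam, co$samples$sample_id)
  known <- snv_calls(chrom = c(co$sites$chrom[1], "chrElse"),
                     pos = c(co$sites$pos[1], 100L),
                     ref = c(co$sites$ref[1], "A"),
                     alt = c(co$sites$alt[1], "C"))
  w <- capture_warnings(rep <- sensitivity_projection(known, panel))
  expect_true(any(grepl("absent", w)))
  expect_true(any(grepl("skipped", w)))
  expect_equal(rep$aggregate$n_assessed, 1L)
  expect_error(sensitivity_projection(known, panel[1]), "at least 2")
})
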