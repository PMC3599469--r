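fake_test_evidence <- function(variants, alt, alt_long, depth = 30L) {
  data.frame(chrom = variants$chrom, pos = variants$pos, alt = variants$alt,
             depth = depth, alt_count = alt, alt_count_long_mate = alt_long,
             alt_count_short_mate = alt - alt_long)
}

test_that("mate classification follows the configured mode", {
  # 50/35 chemistry: by length, 35-base reads are the short mate
  cfg_len <- mate_class_config(length_cutoff = 50)
  expect_equal(mate_class(35, "second", cfg_len), "short_mate")
  expect_equal(mate_class(50, "first", cfg_len), "long_mate")  # boundary
  expect_equal(mate_class(35, "unpaired", cfg_len), "long_mate")
  # dynamic cutoff: longest read at the locus
  expect_equal(mate_class(c(35, 50), c("second", "first"),
                          mate_class_config(), length_cutoff = 50),
               c("short_mate", "long_mate"))
  # by ordinal
  cfg_ord <- mate_class_config(mode = "by-ordinal")
  expect_equal(mate_class(50, "second", cfg_ord), "short_mate")
  expect_equal(mate_class(35, "first", cfg_ord), "long_mate")
  expect_equal(mate_class(35, "unpaired", cfg_ord), "long_mate")
})

test_that("variants evident only in short mates are binned", {
  toy <- toy_alignments()
  v <- snv_calls("chr1", c(10L, 20L, 30L), ref = "A", alt = "C")
  ev <- fake_test_evidence(v, alt = c(4L, 4L, 0L), alt_long = c(0L, 1L, 0L))
  out <- apply_pe_bias_filter(v, toy$bam, evidence = ev)
  expect_equal(out$binned$pos, 10L)                      # short-mate only
  expect_equal(out$kept$pos, c(20L, 30L))                # balanced / no support
  expect_match(out$binned$info, "FAVR_BIN=short_mate_only")
  # zero-support variants are kept but flagged for audit
  expect_match(out$kept$info[2], "FAVR_PE=no_support_observed")
  expect_equal(out$provenance$reason, c("short_mate_only", "",
                                        "no_support_observed"))
})

test_that("short-mate artefacts in a simulated test sample are caught", {
  co <- cohort_main()
  test_calls <- co$calls[["S01"]]
  out <- apply_pe_bias_filter(test_calls, co$samples$bam[1])
  cls_binned <- site_class_of(co, out$binned)
  expect_true(all(cls_binned == "artefact_pe"))
  # every planted short-mate artefact called in S01 is binned
  pe_sites <- co$sites$site_id[co$sites$class == "artefact_pe"]
  expect_true(all(pe_sites[pe_sites %in% test_calls$id] %in% out$binned$id))
  # partition
  expect_equal(nrow(out$kept) + nrow(out$binned), nrow(test_calls))
})

test_that("the filter is the identity when every variant has long-mate support", {
  co <- cohort_main()
  test_calls <- co$calls[["S01"]]
  keep_cls <- site_class_of(co, test_calls) != "artefact_pe"
  balanced <- test_calls[keep_cls, ]
  out <- apply_pe_bias_filter(balanced, co$samples$bam[1])
  expect_equal(nrow(out$binned), 0L)
  expect_equal(out$kept$id, balanced$id)
})
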