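# Evidence injection: hand-specified per-comparator counts, so threshold
# semantics can be pinned exactly without alignment files.
fake_panel_evidence <- function(variants, alt_counts, depth = 30L) {
  lapply(seq_len(ncol(alt_counts)), function(k)
    data.frame(chrom = variants$chrom, pos = variants$pos,
               alt = variants$alt, depth = depth,
               alt_count = alt_counts[, k],
               alt_count_long_mate = alt_counts[, k],
               alt_count_short_mate = 0L))
}

fake_config <- function(n = 8L, read_threshold = 1L, percent_threshold = 30) {
  toy <- toy_alignments()
  filter_config(stats::setNames(rep(toy$bam, n), sprintf("c%d", seq_len(n))),
                read_threshold = read_threshold,
                percent_threshold = percent_threshold)
}

test_that("variant-like means alt reads at or above the read threshold", {
  expect_true(is_variant_like(1, read_threshold = 1))
  expect_false(is_variant_like(0, read_threshold = 1))
  expect_false(is_variant_like(1, read_threshold = 2))
  expect_true(is_variant_like(2, read_threshold = 2))
  expect_error(is_variant_like(1, read_threshold = 0))
})

test_that("comparator percentage uses the full panel as denominator", {
  expect_equal(comparator_percent(c(1, 2, 0, 0, 0, 0, 0, 0)), 25)
  expect_equal(comparator_percent(rep(0, 8)), 0)
  expect_equal(comparator_percent(rep(1, 8)), 100)
  # zero-coverage comparators still count in the denominator
  expect_equal(comparator_percent(c(3, 0, 0, 0), panel_size = 4), 25)
  expect_error(comparator_percent(integer(0)), "empty")
})

test_that("the percent threshold boundary discards (kept only strictly below)", {
  v <- snv_calls(chrom = "chr1", pos = c(10L, 20L, 30L, 40L), ref = "A",
                 alt = "C")
  # alt reads in 2 / 3 / 8 / 0 of 8 comparators -> 25 / 37.5 / 100 / 0 %
  alt <- rbind(c(1, 1, 0, 0, 0, 0, 0, 0),
               c(1, 1, 1, 0, 0, 0, 0, 0),
               rep(1, 8),
               rep(0, 8))
  out <- apply_rare_and_true(v, fake_config(), evidence = fake_panel_evidence(v, alt))
  expect_equal(out$kept$pos, c(10L, 40L))
  expect_equal(out$binned$pos, c(20L, 30L))
  expect_equal(out$provenance$percent_variant_like, c(25, 37.5, 100, 0))
  # at 100% only a full panel discards
  out100 <- apply_rare_and_true(v, fake_config(percent_threshold = 100),
                                evidence = fake_panel_evidence(v, alt))
  expect_equal(out100$binned$pos, 30L)
  seven <- rbind(c(rep(1, 7), 0))
  v1 <- v[1, ]
  out7 <- apply_rare_and_true(v1, fake_config(percent_threshold = 100),
                              evidence = fake_panel_evidence(v1, seven))
  expect_equal(nrow(out7$binned), 0L)
})

test_that("raising either threshold never shrinks the kept set", {
  co <- cohort_main()
  test_calls <- co$calls[["S01"]]
  panel <- main_comparators(co)
  ev <- collect_panel_evidence(test_calls, panel)
  kept_sets <- list()
  for (t in c(1L, 2L, 3L)) {
    for (p in c(10, 30, 50, 100)) {
      cfg <- filter_config(panel, read_threshold = t, percent_threshold = p)
      out <- apply_rare_and_true(test_calls, cfg, evidence = ev)
      kept_sets[[paste(t, p)]] <- out$kept$id
      expect_equal(nrow(out$kept) + nrow(out$binned), nrow(test_calls))
    }
  }
  for (t in c(1L, 2L)) for (p in c(10, 30, 50, 100))
    expect_true(all(kept_sets[[paste(t, p)]] %in%
                      kept_sets[[paste(t + 1L, p)]]))
  for (p in c(10, 30, 50)) for (t in c(1L, 2L, 3L)) {
    nxt <- c(`10` = 30, `30` = 50, `50` = 100)[[as.character(p)]]
    expect_true(all(kept_sets[[paste(t, p)]] %in% kept_sets[[paste(t, nxt)]]))
  }
})

test_that("filter decisions match a brute-force SAM scan of the comparators", {
  co <- cohort_main()
  test_calls <- co$calls[["S01"]]
  panel <- main_comparators(co)
  out <- apply_rare_and_true(test_calls, filter_config(panel))
  sam_reads <- lapply(co$samples$sam[2:9], parse_sam_text)
  idx <- seq(1L, nrow(test_calls), by = 2L)  # every other variant
  for (i in idx) {
    expected <- rare_true_oracle_decision(sam_reads, test_calls$chrom[i],
                                          test_calls$pos[i],
                                          test_calls$alt[i])
    expect_equal(out$provenance$decision[i], expected,
                 info = paste("variant", test_calls$id[i]))
  }
})

test_that("filtering is deterministic and order-preserving", {
  co <- cohort_main()
  test_calls <- co$calls[["S01"]]
  cfg <- filter_config(main_comparators(co))
  out1 <- apply_rare_and_true(test_calls, cfg)
  out2 <- apply_rare_and_true(test_calls, cfg)
  expect_identical(out1$provenance, out2$provenance)
  expect_identical(out1$kept$id, out2$kept$id)
  # order within each partition follows input order
  expect_equal(out1$kept$id,
               test_calls$id[test_calls$id %in% out1$kept$id])
  expect_equal(out1$binned$id,
               test_calls$id[test_calls$id %in% out1$binned$id])
})

test_that("panel configuration is validated", {
  toy <- toy_alignments()
  expect_error(filter_config(character(0)))
  expect_error(filter_config(c(a = toy$bam, a = toy$bam)), "unique")
  expect_error(filter_config(c(a = "no/such.bam")), "not found")
  expect_warning(filter_config(c(S01 = toy$bam), test_sample = "S01"),
                 "comparator panel")
  expect_error(filter_config(c(a = toy$bam), percent_threshold = 0))
})
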