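test_that("the same seed reproduces the cohort byte for byte", {
  cfg <- simulation_config(seed = 77, n_samples = 3, reference_length = 6000,
                           mean_coverage = 15, n_true_rare = 5, n_common = 3,
                           n_artefact_mapping = 3, deletion_read_rate = 0.02)
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  co1 <- simulate_cohort(cfg, d1)
  co2 <- simulate_cohort(cfg, d2)
  for (f in c("reference.fasta", "S01.sam", "S02.sam", "S03.sam",
              "S01.bam", "S01.candidates.vcf", "truth.tsv",
              "truth_plants.tsv")) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 info = f)
  }
  # a different seed changes the data
  co3 <- simulate_cohort(simulation_config(seed = 78, n_samples = 3,
                                           reference_length = 6000,
                                           mean_coverage = 15,
                                           n_true_rare = 5, n_common = 3,
                                           n_artefact_mapping = 3,
                                           deletion_read_rate = 0.02),
                         file.path(tempdir(), "det3"))
  expect_false(unname(tools::md5sum(file.path(d1, "S01.sam"))) ==
                 unname(tools::md5sum(file.path(tempdir(), "det3",
                                                "S01.sam"))))
})

test_that("planted support rounds to the nearest realizable fraction", {
  rt <- flat_read_table(n_long = 15L, n_short = 15L)
  set.seed(1)
  res <- plant_read_support(rt, pos = 10L, alt = "G", target_fraction = 0.5)
  expect_equal(res$planted, 15L)
  expect_equal(res$depth, 30L)
  expect_equal(res$achieved_fraction, 0.5)
  # mutated reads carry the alternate base exactly at the offset
  n_alt <- sum(substr(res$reads$seq, 10L, 10L) == "G")
  expect_equal(n_alt, 15L)
  expect_true(all(substr(res$reads$seq, 9L, 9L) == "A"))
  # target zero leaves reads untouched
  res0 <- plant_read_support(rt, 10L, "G", 0)
  expect_identical(res0$reads$seq, rt$seq)
  expect_equal(res0$planted, 0L)
})

test_that("a short-mate restriction caps planting at the available short reads", {
  rt <- flat_read_table(n_long = 6L, n_short = 4L)
  set.seed(1)
  res <- plant_read_support(rt, 10L, "G", 0.5, restrict = "short-mate")
  expect_equal(res$planted, 4L)
  expect_equal(res$achieved_fraction, 0.4)
  mutated <- substr(res$reads$seq, 10L, 10L) == "G"
  expect_true(all(bitwAnd(res$reads$flag[mutated], 128L) > 0L))
  # no short reads at all: infeasible, reads unchanged
  rt_long <- flat_read_table(n_long = 5L, n_short = 0L)
  bad <- plant_read_support(rt_long, 10L, "G", 0.5, restrict = "short-mate")
  expect_false(bad$feasible)
  expect_identical(bad$reads$seq, rt_long$seq)
})

test_that("unrestricted planting keeps mate-balanced support", {
  rt <- flat_read_table(n_long = 10L, n_short = 10L)
  for (s in 1:20) {
    set.seed(s)
    res <- plant_read_support(rt, 10L, "G", 0.15)
    mutated <- substr(res$reads$seq, 10L, 10L) == "G"
    expect_true(any(bitwAnd(res$reads$flag[mutated], 128L) == 0L))
  }
})

test_that("emitted alignments reproduce the planted ground truth exactly", {
  co <- cohort_main()  # zero sequencing error
  for (sid in c("S01", "S05")) {
    pl <- co$plants[co$plants$sample_id == sid, ]
    loci <- co$sites[match(pl$site_id, co$sites$site_id), ]
    ev <- collect_pileup_evidence(
      co$samples$bam[co$samples$sample_id == sid],
      data.frame(chrom = loci$chrom, pos = loci$pos, alt = loci$alt))
    expect_equal(ev$alt_count, pl$alt_count)
    expect_equal(ev$depth, pl$depth)
    expect_equal(pl$planted_alt, pl$alt_count)
  }
  # short-mate artefacts have no long-mate support in the carrier's reads
  pe <- co$sites[co$sites$class == "artefact_pe", ]
  ev_pe <- collect_pileup_evidence(co$samples$bam[1],
                                   data.frame(chrom = pe$chrom, pos = pe$pos,
                                              alt = pe$alt))
  expect_true(all(ev_pe$alt_count_long_mate == 0L))
  expect_true(all(ev_pe$alt_count >= 1L))
})

test_that("artefact alt fractions stay sub-homozygous", {
  co <- cohort_main()
  art <- co$plants$class %in% c("artefact_mapping", "artefact_pe")
  expect_true(all(co$plants$achieved_fraction[art] <= 0.5))
  expect_true(all(co$plants$alt_count[art] >= 1L))
})

test_that("candidate VCFs contain exactly the sites with called support", {
  co <- cohort_main()
  cfg <- co$config
  for (sid in c("S01", "S07")) {
    calls <- co$calls[[sid]]
    # every call is backed by at least one alt read in that sample's BAM
    ev <- collect_pileup_evidence(
      co$samples$bam[co$samples$sample_id == sid], calls)
    expect_true(all(ev$alt_count >= cfg$call_min_reads))
    # and every planted site with support in this sample is called
    pl <- co$plants[co$plants$sample_id == sid &
                      co$plants$alt_count >= cfg$call_min_reads, ]
    expect_setequal(pl$site_id, calls$id)
  }
})

test_that("cousin sharing follows the kinship probability", {
  co <- get_fixture("coh_cousins", function() {
    simulate_cohort(
      simulation_config(seed = 13, n_samples = 2, n_cousin_pairs = 1,
                        reference_length = 30000, mean_coverage = 10,
                        n_true_rare = 400),
      file.path(tempdir(), "coh_cousins"))
  })
  rare <- co$sites[co$sites$class == "true_rare", ]
  shared <- sum(rare$n_carriers == 2L)
  # Binomial(400, 0.125): mean 50, sd 6.6; allow 3 sd
  expect_gt(shared, 50 - 3 * sqrt(400 * 0.125 * 0.875))
  expect_lt(shared, 50 + 3 * sqrt(400 * 0.125 * 0.875))
  # each cousin carries the configured number of rare sites
  carried <- strsplit(rare$carriers, ",", fixed = TRUE)
  expect_equal(sum(vapply(carried, function(x) "S01" %in% x, TRUE)), 400L)
  expect_equal(sum(vapply(carried, function(x) "S02" %in% x, TRUE)), 400L)
})

test_that("an oversized site plan is rejected up front", {
  expect_error(
    simulate_cohort(simulation_config(seed = 1, n_samples = 1,
                                      reference_length = 1000,
                                      fragment_length = 120,
                                      n_true_rare = 5000),
                    file.path(tempdir(), "never")),
    "infeasible")
})

test_that("simulation configs are validated", {
  expect_error(simulation_config(n_samples = 2, n_cousin_pairs = 2))
  expect_error(simulation_config(read_length_short = 10))
  expect_error(simulation_config(fragment_length = 60))
  expect_error(simulation_config(artefact_fraction = c(0.5, 0.2)))
})
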