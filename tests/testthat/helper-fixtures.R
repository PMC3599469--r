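# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# Mixed cohort: a test sample plus 9 others carrying private rare variants,
# common variants, recurrent mapping artefacts and short-mate artefacts,
# with a sprinkling of deletion-bearing reads.
cohort_main <- function() get_fixture("coh_main", function() {
  simulate_cohort(
    simulation_config(seed = 42, n_samples = 10, reference_length = 12000,
                      mean_coverage = 25, n_true_rare = 20, n_common = 8,
                      n_artefact_mapping = 15, n_artefact_pe = 5,
                      deletion_read_rate = 0.03),
    file.path(tempdir(), "coh_main"))
})

main_comparators <- function(cohort = cohort_main()) {
  stats::setNames(cohort$samples$bam[2:9], cohort$samples$sample_id[2:9])
}

site_class_of <- function(cohort, snvs) {
  cohort$sites$class[match(snvs$id, cohort$sites$site_id)]
}

# Hand-built alignment fixture with known per-read bases at chosen loci.
# Reads (all on chrToy, reference arbitrary since CIGARs are explicit):
#   r1 first-of-pair  len 10, pos 10, base at 15 = alt C,   mapq 60
#   r2 second-of-pair len  8, pos 12, base at 15 = ref A,   mapq 60
#   r3 unpaired       len 10, pos 11, base at 15 = alt C,   mapq 60
#   r4 unpaired       len 12, pos  8, 4M4D8M: deletion spans 12..15 -> GAP
#   r5 duplicate      len 10, pos 10, base at 15 = alt C
#   r6 low mapq (5)   len 10, pos 10, base at 15 = alt C
#   r7 low baseq (10) len 10, pos 10, base at 15 = alt C
toy_alignments <- function() get_fixture("toy_sam", function() {
  dir <- file.path(tempdir(), "toy_sam")
  dir.create(dir, showWarnings = FALSE)
  q <- function(n, bad_at = 0L) {
    s <- strrep("I", n)
    if (bad_at > 0L) substr(s, bad_at, bad_at) <- "+"  # phred 10
    s
  }
  seq_with <- function(n, at, base) {
    s <- strrep("A", n)
    substr(s, at, at) <- base
    s
  }
  rows <- list(
    c("r1",  "99", "chrToy", "10", "60", "10M", "=", "12",  "10",
      seq_with(10, 6, "C"), q(10)),
    c("r2", "147", "chrToy", "12", "60",  "8M", "=", "10", "-10",
      seq_with(8, 4, "A"), q(8)),
    c("r3",   "0", "chrToy", "11", "60", "10M", "*",  "0",   "0",
      seq_with(10, 5, "C"), q(10)),
    c("r4",   "0", "chrToy",  "8", "60", "4M4D8M", "*", "0", "0",
      seq_with(12, 5, "C"), q(12)),
    c("r5", "1123", "chrToy", "10", "60", "10M", "=", "12", "10",
      seq_with(10, 6, "C"), q(10)),
    c("r6",   "0", "chrToy", "10",  "5", "10M", "*", "0", "0",
      seq_with(10, 6, "C"), q(10)),
    c("r7",   "0", "chrToy", "10", "60", "10M", "*", "0", "0",
      seq_with(10, 6, "C"), q(10, bad_at = 6))
  )
  sam <- file.path(dir, "toy.sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               "@SQ\tSN:chrToy\tLN:100",
               vapply(rows, paste, "", collapse = "\t")), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "toy"), overwrite = TRUE,
                          indexDestination = TRUE)
  list(sam = sam, bam = bam)
})

# Cohort with family-shared sites planted at low alt fraction in the
# relative while candidate calling demands 25% — so the relative's VCF
# misses them even though its reads carry the allele.
cohort_family <- function() get_fixture("coh_fam", function() {
  simulate_cohort(
    simulation_config(seed = 11, n_samples = 2, reference_length = 9000,
                      mean_coverage = 25, n_true_rare = 10,
                      n_shared_family = 8,
                      shared_family_fraction = c(0.12, 0.18),
                      call_min_fraction = 0.25),
    file.path(tempdir(), "coh_fam"))
})

# value of an INFO key, NA when absent
info_values <- function(info, key) {
  m <- regexpr(paste0("(?<=^|;)", key, "=[^;]*"), info, perl = TRUE)
  out <- rep(NA_character_, length(info))
  out[m != -1] <- sub(paste0(key, "="), "", regmatches(info, m), fixed = TRUE)
  out
}

write_vcf_fixture <- function(records, path,
                              header = "##fileformat=VCFv4.2") {
  cols <- "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  writeLines(c(header, cols, records), path)
  path
}

# A read table in the layout plant_read_support() expects: paired reads of
# the two mate classes, all starting at the same position.
flat_read_table <- function(n_long, n_short, len_long = 50L, len_short = 35L,
                            start = 1L) {
  n <- n_long + n_short
  data.frame(
    qname = sprintf("q%03d", seq_len(n)),
    flag = c(rep(99L, n_long), rep(147L, n_short)),
    start = rep(start, n),
    len = c(rep(len_long, n_long), rep(len_short, n_short)),
    cigar = c(rep(paste0(len_long, "M"), n_long),
              rep(paste0(len_short, "M"), n_short)),
    ref_end = start + c(rep(len_long, n_long), rep(len_short, n_short)) - 1L,
    seq = c(rep(strrep("A", len_long), n_long),
            rep(strrep("A", len_short), n_short)),
    simple = TRUE,
    stringsAsFactors = FALSE
  )
}
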