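# Independent pileup oracle: a from-scratch, read-by-read scan of the
# plain-text SAM form.  Shares no code with the package implementation
# (which reads BAM through Rsamtools).

parse_sam_text <- function(sam_path) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  strsplit(lines, "\t", fixed = TRUE)
}

# depth / alt counts / mate split at one locus, by walking every read's CIGAR
sam_pileup_oracle <- function(sam_reads, chrom, pos, alt,
                              min_base_quality = 0, min_mapping_quality = 0,
                              include_duplicates = FALSE) {
  depth <- 0L; alt_n <- 0L
  lens <- integer(0); ords <- character(0); alts <- logical(0)
  for (f in sam_reads) {
    if (f[3] != chrom) next
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L) next     # unmapped
    if (bitwAnd(flag, 256L) > 0L) next   # secondary
    if (bitwAnd(flag, 2048L) > 0L) next  # supplementary
    if (!include_duplicates && bitwAnd(flag, 1024L) > 0L) next
    if (as.integer(f[5]) < min_mapping_quality) next
    start <- as.integer(f[4])
    cigar <- f[6]
    nums <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
    ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
    refc <- start; qc <- 0L
    hit <- NA_integer_  # query index of pos; 0 = gap
    for (k in seq_along(ops)) {
      op <- ops[k]; l <- nums[k]
      if (op %in% c("M", "=", "X")) {
        if (pos >= refc && pos <= refc + l - 1L) { hit <- qc + (pos - refc) + 1L; break }
        refc <- refc + l; qc <- qc + l
      } else if (op %in% c("I", "S")) {
        qc <- qc + l
      } else if (op %in% c("D", "N")) {
        if (pos >= refc && pos <= refc + l - 1L) { hit <- 0L; break }
        refc <- refc + l
      }
    }
    if (is.na(hit) || hit == 0L) next
    bq <- utf8ToInt(substr(f[11], hit, hit)) - 33L
    if (bq < min_base_quality) next
    depth <- depth + 1L
    is_alt <- substr(f[10], hit, hit) == alt
    if (is_alt) alt_n <- alt_n + 1L
    lens <- c(lens, nchar(f[10]))
    ords <- c(ords, if (bitwAnd(flag, 1L) == 0L) "unpaired"
                    else if (bitwAnd(flag, 64L) > 0L) "first" else "second")
    alts <- c(alts, is_alt)
  }
  if (depth == 0L)
    return(list(depth = 0L, alt_count = 0L, alt_long = 0L, alt_short = 0L))
  cutoff <- max(lens)
  short <- ords != "unpaired" & lens < cutoff
  list(depth = depth, alt_count = alt_n,
       alt_long = sum(alts & !short), alt_short = sum(alts & short))
}

# Brute-force Rare and True decision from SAM text for one variant
rare_true_oracle_decision <- function(sam_reads_list, chrom, pos, alt,
                                      read_threshold = 1L,
                                      percent_threshold = 30) {
  nlike <- sum(vapply(sam_reads_list, function(rr)
    sam_pileup_oracle(rr, chrom, pos, alt)$alt_count >= read_threshold,
    logical(1)))
  if (100 * nlike >= percent_threshold * length(sam_reads_list))
    "binned" else "kept"
}
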