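#' Quality gates for pileup evidence counting
#'
#' The filters count "any read" carrying the alternate base, so the defaults
#' apply no base- or mapping-quality cutoff.  Duplicate-flagged reads are
#' ignored by default: duplicate removal is expected upstream, and a
#' duplicated artefact read must not be double-counted as independent
#' evidence.  Unmapped, secondary and supplementary alignments are always
#' excluded.
#'
#' @param min_base_quality Minimum phred base quality at the locus (default 0).
#' @param min_mapping_quality Minimum mapping quality (default 0).
#' @param include_duplicates Count duplicate-flagged reads? Default `FALSE`.
#' @return A `favr_gates` list.
#' @export
quality_gates <- function(min_base_quality = 0L, min_mapping_quality = 0L,
                          include_duplicates = FALSE) {
  stopifnot(min_base_quality >= 0L, min_mapping_quality >= 0L,
            is.logical(include_duplicates))
  structure(list(min_base_quality = as.integer(min_base_quality),
                 min_mapping_quality = as.integer(min_mapping_quality),
                 include_duplicates = isTRUE(include_duplicates)),
            class = "favr_gates")
}

#' Mate classification for imbalanced paired-end chemistries
#'
#' Imbalanced chemistries sequence mates of unequal length (e.g. 50- and
#' 35-base SOLiD mates) and the shorter mate is artefact-prone.  Reads can be
#' classified either by length (`"by-length"`: reads shorter than
#' `length_cutoff` are short-mate; with `length_cutoff = NULL` the cutoff is
#' the longest read length observed at the locus, so the 35-base mate of a
#' 50/35 pair is short wherever a 50-base read is present) or by mate ordinal
#' (`"by-ordinal"`: the library preparation fixes which mate is short).
#' Unpaired reads are long-mate in both modes.
#'
#' @param mode `"by-length"` (default) or `"by-ordinal"`.
#' @param length_cutoff Reads shorter than this many bases are short-mate;
#'   `NULL` (default) uses the longest observed read length at each locus.
#' @param short_mate_ordinal `"first"` or `"second"` (default) of pair, used
#'   in by-ordinal mode.
#' @return A `favr_mate_config` list.
#' @export
mate_class_config <- function(mode = c("by-length", "by-ordinal"),
                              length_cutoff = NULL,
                              short_mate_ordinal = c("second", "first")) {
  mode <- match.arg(mode)
  short_mate_ordinal <- match.arg(short_mate_ordinal)
  if (!is.null(length_cutoff)) {
    length_cutoff <- as.integer(length_cutoff)
    stopifnot(length_cutoff >= 1L)
  }
  structure(list(mode = mode, length_cutoff = length_cutoff,
                 short_mate_ordinal = short_mate_ordinal),
            class = "favr_mate_config")
}

#' Classify a read observation as long-mate or short-mate
#'
#' @param read_length Read length in bases.
#' @param mate_ordinal `"first"`, `"second"` or `"unpaired"`.
#' @param config A [mate_class_config()].
#' @param length_cutoff Resolved length cutoff for by-length mode (required
#'   when `config$length_cutoff` is `NULL`; callers working from a pileup use
#'   the longest observed read length at the locus).
#' @return Character vector of `"long_mate"` / `"short_mate"`.
#' @examples
#' mate_class(35, "second", mate_class_config(length_cutoff = 50))
#' @export
mate_class <- function(read_length, mate_ordinal, config = mate_class_config(),
                       length_cutoff = NULL) {
  mate_ordinal <- as.character(mate_ordinal)
  stopifnot(all(mate_ordinal %in% c("first", "second", "unpaired")))
  paired <- mate_ordinal != "unpaired"
  short <- if (config$mode == "by-length") {
    cutoff <- config$length_cutoff %||% length_cutoff
    if (is.null(cutoff))
      stop("by-length mate classification needs a length cutoff", call. = FALSE)
    paired & (read_length < cutoff)
  } else {
    paired & (mate_ordinal == config$short_mate_ordinal)
  }
  ifelse(short, "short_mate", "long_mate")
}

bam_index_path <- function(bam) {
  cands <- c(paste0(bam, ".bai"), sub("\\.bam$", ".bai", bam))
  cands[file.exists(cands)][1]
}

## Walk one CIGAR over the reference and return the 1-based query offset of
## `pos`, 0L if a deletion/skip spans it (a GAP observation), or NA if the
## read does not cover it.  Soft clips consume query only; hard clips and
## padding consume neither.
query_offset <- function(ops, lens, start, pos) {
  ref <- start
  q <- 0L
  for (k in seq_along(ops)) {
    op <- ops[k]
    l <- lens[k]
    if (op == "M" || op == "=" || op == "X") {
      if (pos >= ref && pos < ref + l) return(q + (pos - ref) + 1L)
      ref <- ref + l
      q <- q + l
    } else if (op == "I" || op == "S") {
      q <- q + l
    } else if (op == "D" || op == "N") {
      if (pos >= ref && pos < ref + l) return(0L)
      ref <- ref + l
    }
  }
  NA_integer_
}

#' Collect per-locus read evidence from an alignment file
#'
#' For each requested locus, counts qualifying read observations (`depth`),
#' those carrying the alternate base (`alt_count`), and splits the alternate
#' support by mate class (`alt_count_long_mate` / `alt_count_short_mate`).
#' Reads whose alignment places a deletion or reference skip across the locus
#' contribute neither to depth nor to alternate support.  Loci with no
#' coverage (or on a chromosome absent from the BAM header, with a warning)
#' yield zero counts.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param loci A data frame with columns `chrom`, `pos` and `alt` (a
#'   [snv_calls()] table qualifies).
#' @param gates A [quality_gates()] object.
#' @param mate_config A [mate_class_config()] object.
#' @return A data frame, one row per locus in input order, with columns
#'   `chrom`, `pos`, `alt`, `depth`, `alt_count`, `alt_count_long_mate`,
#'   `alt_count_short_mate` and `max_read_length`.
#' @export
collect_pileup_evidence <- function(bam, loci, gates = quality_gates(),
                                    mate_config = mate_class_config()) {
  if (!file.exists(bam))
    stop("alignment file not found: ", bam, call. = FALSE)
  if (is.na(bam_index_path(bam)))
    stop("missing BAM index (.bai) for: ", bam,
         " — the file must be coordinate-sorted and indexed", call. = FALSE)
  stopifnot(is.data.frame(loci), all(c("chrom", "pos", "alt") %in% names(loci)))
  n <- nrow(loci)
  out <- data.frame(chrom = as.character(loci$chrom),
                    pos = as.integer(loci$pos),
                    alt = as.character(loci$alt),
                    depth = integer(n), alt_count = integer(n),
                    alt_count_long_mate = integer(n),
                    alt_count_short_mate = integer(n),
                    max_read_length = integer(n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)

  bf <- Rsamtools::BamFile(bam)
  targets <- Rsamtools::scanBamHeader(bf)$targets
  known <- out$chrom %in% names(targets)
  if (any(!known))
    warning("chromosome(s) absent from BAM header of ", basename(bam), ": ",
            paste(unique(out$chrom[!known]), collapse = ", "),
            "; reporting zero depth", call. = FALSE)
  idx <- which(known)
  if (length(idx) == 0L) return(out)

  gr <- GenomicRanges::GRanges(out$chrom[idx],
                               IRanges::IRanges(out$pos[idx], out$pos[idx]))
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (gates$include_duplicates) NA else FALSE
  )
  need_qual <- gates$min_base_quality > 0L
  param <- Rsamtools::ScanBamParam(
    which = gr, flag = flag,
    what = c("flag", "pos", "mapq", "cigar", "seq",
             if (need_qual) "qual")
  )
  res <- Rsamtools::scanBam(bf, param = param)

  for (j in seq_along(idx)) {
    b <- res[[j]]
    if (length(b$pos) == 0L) next
    locus_pos <- out$pos[idx[j]]
    alt <- out$alt[idx[j]]
    keep <- !is.na(b$pos) & !is.na(b$cigar) &
      (is.na(b$mapq) | b$mapq >= gates$min_mapping_quality)
    if (!any(keep)) next
    flags <- b$flag[keep]
    starts <- b$pos[keep]
    cigars <- b$cigar[keep]
    seqs <- as.character(b$seq)[keep]
    quals <- if (need_qual) as.character(b$qual)[keep]
    # all-match CIGARs (the vast majority) take an arithmetic fast path
    m <- length(flags)
    simple <- grepl("^[0-9]+M$", cigars)
    ops <- lens <- vector("list", m)
    if (!all(simple)) {
      ops[!simple] <- GenomicAlignments::explodeCigarOps(cigars[!simple])
      lens[!simple] <- GenomicAlignments::explodeCigarOpLengths(cigars[!simple])
    }
    obs_base <- character(m)
    obs_len <- integer(m)
    obs_ord <- character(m)
    use <- logical(m)
    for (r in seq_len(m)) {
      off <- if (simple[r]) {
        d <- locus_pos - starts[r]
        if (d >= 0L && d < nchar(seqs[r])) d + 1L else NA_integer_
      } else query_offset(ops[[r]], lens[[r]], starts[r], locus_pos)
      if (is.na(off) || off == 0L) next  # uncovered or GAP
      if (need_qual) {
        bq <- utf8ToInt(substr(quals[r], off, off)) - 33L
        if (length(bq) && !is.na(bq) && bq < gates$min_base_quality) next
      }
      use[r] <- TRUE
      obs_base[r] <- substr(seqs[r], off, off)
      obs_len[r] <- nchar(seqs[r])
      f <- flags[r]
      obs_ord[r] <- if (bitwAnd(f, 1L) == 0L) "unpaired"
        else if (bitwAnd(f, 64L) > 0L) "first" else "second"
    }
    if (!any(use)) next
    obs_base <- obs_base[use]; obs_len <- obs_len[use]; obs_ord <- obs_ord[use]
    depth <- length(obs_base)
    is_alt <- obs_base == alt
    cls <- mate_class(obs_len, obs_ord, mate_config,
                      length_cutoff = max(obs_len))
    out$depth[idx[j]] <- depth
    out$alt_count[idx[j]] <- sum(is_alt)
    out$alt_count_long_mate[idx[j]] <- sum(is_alt & cls == "long_mate")
    out$alt_count_short_mate[idx[j]] <- sum(is_alt & cls == "short_mate")
    out$max_read_length[idx[j]] <- max(obs_len)
  }
  out
}

#' Collect pileup evidence for a variant list across a panel of BAM files
#'
#' @param loci A data frame with `chrom`, `pos`, `alt` columns.
#' @param panel Named character vector of BAM paths; names are sample ids.
#' @param gates A [quality_gates()] object.
#' @param mate_config A [mate_class_config()] object.
#' @return Named list (one element per panel member, in panel order) of
#'   [collect_pileup_evidence()] data frames.
#' @export
collect_panel_evidence <- function(loci, panel, gates = quality_gates(),
                                   mate_config = mate_class_config()) {
  panel <- normalise_panel(panel)
  lapply(panel, function(bam)
    collect_pileup_evidence(bam, loci, gates = gates,
                            mate_config = mate_config))
}

## Accept a named vector of BAM paths; fill missing names from file names and
## require uniqueness so percentage denominators are well-defined.
normalise_panel <- function(panel) {
  panel <- unlist(panel, use.names = TRUE)
  stopifnot(length(panel) >= 1L)
  nm <- names(panel) %||% rep("", length(panel))
  fill <- !nzchar(nm)
  nm[fill] <- sub("\\.bam$", "", basename(panel[fill]))
  if (anyDuplicated(nm))
    stop("panel sample ids must be unique: ",
         paste(nm[duplicated(nm)], collapse = ", "), call. = FALSE)
  missing <- !file.exists(panel)
  if (any(missing))
    stop("alignment file(s) not found: ",
         paste(panel[missing], collapse = ", "), call. = FALSE)
  names(panel) <- nm
  panel
}
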