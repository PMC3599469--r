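#' Read a position-exclusion table
#'
#' Reads a tab-separated table of known-variant positions (a dbSNP-style
#' export).  Accepted layouts, detected from the column count: `chrom pos`,
#' `chrom pos alt` or `chrom pos ref alt`.  A header line is detected (and
#' skipped) when the second field of the first line is not numeric.  When the
#' table supplies alternate alleles, exclusion matches on (chrom, pos, alt);
#' otherwise on (chrom, pos) — database exports vary in what they record.
#'
#' @param path Path to the tab-separated table.
#' @return A `favr_exclusions` object.
#' @export
read_position_exclusions <- function(path) {
  if (!file.exists(path))
    stop("exclusion table not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(position_exclusions(data.frame(chrom = character(),
                                          pos = integer())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L))
    stop("malformed exclusion table line ", which(nf < 2L)[1], " in ", path,
         ": expected at least chrom<TAB>pos", call. = FALSE)
  start <- 1L
  if (is.na(suppressWarnings(as.integer(fields[[1]][2])))) start <- 2L
  if (start > length(fields))
    return(position_exclusions(data.frame(chrom = character(),
                                          pos = integer())))
  fields <- fields[start:length(fields)]
  ncols <- min(lengths(fields))
  chrom <- vapply(fields, `[`, "", 1L)
  pos <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  bad <- which(is.na(pos))
  if (length(bad))
    stop("malformed exclusion table line ", bad[1] + start - 1L, " in ", path,
         ": position is not an integer", call. = FALSE)
  df <- data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  if (ncols >= 4L) {
    df$ref <- toupper(vapply(fields, `[`, "", 3L))
    df$alt <- toupper(vapply(fields, `[`, "", 4L))
  } else if (ncols == 3L) {
    df$alt <- toupper(vapply(fields, `[`, "", 3L))
  }
  position_exclusions(df)
}

#' Construct a position-exclusion set
#'
#' @param positions Data frame with columns `chrom`, `pos` and optionally
#'   `alt` (plus ignored extras).  When `alt` is present, matching is per
#'   allele; otherwise per position.
#' @return A `favr_exclusions` object.
#' @export
position_exclusions <- function(positions) {
  stopifnot(is.data.frame(positions),
            all(c("chrom", "pos") %in% names(positions)))
  has_alt <- "alt" %in% names(positions) && all(!is.na(positions$alt))
  structure(list(positions = positions, has_alt = has_alt),
            class = "favr_exclusions")
}

#' Read target regions from a BED file
#'
#' BED intervals are 0-based half-open; the returned `GRanges` follows the
#' usual 1-based closed convention (a BED line `chr1 100 200` covers 1-based
#' positions 101..200).
#'
#' @param path Path to a BED file.
#' @return A `GRanges` of target regions.
#' @export
read_target_regions <- function(path) {
  if (!file.exists(path))
    stop("BED file not found: ", path, call. = FALSE)
  tryCatch(rtracklayer::import(path, format = "bed"),
           error = function(e) stop("failed to parse BED '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
}

#' Remove variants at excluded positions or outside target regions
#'
#' A variant is binned when its position (or position+allele, if the
#' exclusion table records alleles) appears in `exclusions`, or when
#' `regions_keep` is given and the variant lies outside every region.  The
#' kept and binned lists are disjoint, jointly exhaust the input, and each
#' preserves input order.
#'
#' @param variants A [snv_calls()] data frame.
#' @param exclusions A `favr_exclusions` object, or `NULL` for none.
#' @param regions_keep A `GRanges` of regions to keep (e.g. exome target
#'   intervals), or `NULL` for no region restriction.
#' @return A `favr_outcome`.
#' @export
exclude_variants <- function(variants, exclusions = NULL, regions_keep = NULL) {
  variants <- as_snv_calls(variants)
  n <- nrow(variants)
  reason <- rep(NA_character_, n)
  if (!is.null(exclusions)) {
    stopifnot(inherits(exclusions, "favr_exclusions"))
    tab <- exclusions$positions
    hit <- if (exclusions$has_alt) {
      paste(variants$chrom, variants$pos, variants$alt) %in%
        paste(tab$chrom, tab$pos, tab$alt)
    } else {
      paste(variants$chrom, variants$pos) %in% paste(tab$chrom, tab$pos)
    }
    reason[hit] <- "excluded_position"
  }
  if (!is.null(regions_keep) && n > 0L) {
    gr <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos, variants$pos))
    inside <- IRanges::overlapsAny(gr, regions_keep)
    outside <- !inside & is.na(reason)
    reason[outside] <- "outside_target_regions"
  }
  binned_idx <- which(!is.na(reason))
  kept <- variants[is.na(reason), , drop = FALSE]
  binned <- variants[binned_idx, , drop = FALSE]
  if (nrow(binned))
    binned$info <- info_add(binned$info, "FAVR_BIN", reason[binned_idx])
  prov <- data.frame(key = variant_key(variants),
                     decision = ifelse(is.na(reason), "kept", "binned"),
                     reason = ifelse(is.na(reason), "", reason),
                     stringsAsFactors = FALSE)
  favr_outcome(restore_snv(kept, variants), restore_snv(binned, variants),
               prov, tool = "exclude",
               params = list(match = if (is.null(exclusions)) "none"
                             else if (exclusions$has_alt) "position+allele"
                             else "position"))
}

## subsetting a favr_snv drops attributes; restore class and meta
restore_snv <- function(x, template) {
  attr(x, "meta") <- attr(template, "meta") %||% character()
  class(x) <- c("favr_snv", "data.frame")
  rownames(x) <- NULL
  x
}
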