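#' Construct a table of candidate SNV calls
#'
#' The package represents a candidate variant list as an ordinary data frame
#' (class `favr_snv`) with one row per candidate single-nucleotide variant:
#' columns `chrom`, `pos` (1-based), `id`, `ref`, `alt`, `qual`, `filter` and
#' `info`.  The `qual`, `filter` and `info` columns are carried verbatim from
#' input to output so that upstream annotations survive filtering.
#'
#' @param chrom Chromosome names (non-empty strings).
#' @param pos 1-based positions (integers >= 1).
#' @param ref,alt Single reference/alternate bases, one of A/C/G/T, with
#'   `ref != alt` row-wise.
#' @param id,qual,filter,info Pass-through VCF columns; defaults are the VCF
#'   missing value `"."`.
#' @param meta Character vector of VCF header (`##`) lines to carry along.
#' @return A `favr_snv` data frame.
#' @examples
#' snv_calls(chrom = "chr1", pos = 100L, ref = "A", alt = "G")
#' @export
snv_calls <- function(chrom, pos, ref, alt, id = ".", qual = ".",
                      filter = ".", info = ".", meta = character()) {
  n <- length(pos)
  x <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    id = rep_len(as.character(id), n),
    ref = as.character(ref),
    alt = as.character(alt),
    qual = rep_len(as.character(qual), n),
    filter = rep_len(as.character(filter), n),
    info = rep_len(as.character(info), n),
    stringsAsFactors = FALSE
  )
  validate_snv_calls(x)
  attr(x, "meta") <- meta
  class(x) <- c("favr_snv", "data.frame")
  x
}

validate_snv_calls <- function(x) {
  bases <- c("A", "C", "G", "T")
  if (nrow(x) == 0L) return(invisible(x))
  if (any(!nzchar(x$chrom)) || anyNA(x$chrom))
    stop("chrom must be non-empty", call. = FALSE)
  if (anyNA(x$pos) || any(x$pos < 1L))
    stop("pos must be a 1-based position >= 1", call. = FALSE)
  if (!all(x$ref %in% bases) || !all(x$alt %in% bases))
    stop("ref and alt must be single bases (A/C/G/T); ",
         "indels and symbolic alleles are out of scope", call. = FALSE)
  if (any(x$ref == x$alt))
    stop("ref and alt must differ", call. = FALSE)
  invisible(x)
}

empty_snv_calls <- function(meta = character()) {
  x <- data.frame(chrom = character(), pos = integer(), id = character(),
                  ref = character(), alt = character(), qual = character(),
                  filter = character(), info = character(),
                  stringsAsFactors = FALSE)
  attr(x, "meta") <- meta
  class(x) <- c("favr_snv", "data.frame")
  x
}

as_snv_calls <- function(x) {
  if (inherits(x, "favr_snv")) return(x)
  stopifnot(is.data.frame(x), all(c("chrom", "pos", "ref", "alt") %in% names(x)))
  snv_calls(x$chrom, x$pos, x$ref, x$alt,
            id = x$id %||% ".", qual = x$qual %||% ".",
            filter = x$filter %||% ".", info = x$info %||% ".",
            meta = attr(x, "meta") %||% character())
}

#' Read candidate SNV calls from a VCF file
#'
#' Reads a VCF (plain or gzip/bgzip compressed), decomposes multi-allelic
#' records into one row per (record, alternate allele) pair, and keeps only
#' single-nucleotide substitutions.  Non-SNV alleles (indels, MNVs, symbolic
#' or missing alleles) are skipped, never silently: the per-reason counts are
#' attached as the `"skip_log"` attribute.  Input record order (and the order
#' of alternate alleles within a record) is preserved.
#'
#' @param path Path to a VCF file.
#' @return A [snv_calls()] data frame.  Attributes: `"meta"` (the `##` header
#'   lines) and `"skip_log"` (named integer vector of skipped-allele counts).
#' @seealso [write_snv_calls()]
#' @export
read_snv_calls <- function(path) {
  if (!file.exists(path))
    stop("VCF not found: ", path, call. = FALSE)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- v@fix
  skip <- c(indel = 0L, symbolic = 0L, missing = 0L)
  if (nrow(fix) == 0L) {
    out <- empty_snv_calls(meta = v@meta)
    attr(out, "skip_log") <- skip
    return(out)
  }
  alts <- strsplit(ifelse(is.na(fix[, "ALT"]), ".", fix[, "ALT"]), ",",
                   fixed = TRUE)
  nalt <- lengths(alts)
  idx <- rep.int(seq_len(nrow(fix)), nalt)
  alt <- unlist(alts, use.names = FALSE)
  ref <- fix[idx, "REF"]
  bases <- c("A", "C", "G", "T")
  ref_snv <- !is.na(ref) & ref %in% bases
  alt_plain <- !is.na(alt) & grepl("^[ACGTNacgtn]+$", alt)
  is_snv <- ref_snv & alt %in% bases
  sym <- !alt_plain | is.na(ref) | grepl("[^ACGTNacgtn]", ifelse(is.na(ref), "N", ref))
  keep <- which(is_snv)
  dropped <- which(!is_snv)
  if (length(dropped)) {
    d_sym <- sym[dropped] | alt[dropped] %in% c(".", "*")
    d_missing <- is.na(alt[dropped]) | alt[dropped] == "."
    skip["symbolic"] <- sum(d_sym & !d_missing)
    skip["missing"] <- sum(d_missing)
    skip["indel"] <- length(dropped) - skip["symbolic"] - skip["missing"]
  }
  if (length(keep) == 0L) {
    out <- empty_snv_calls(meta = v@meta)
    attr(out, "skip_log") <- skip
    return(out)
  }
  i <- idx[keep]
  out <- snv_calls(
    chrom = fix[i, "CHROM"],
    pos = as.integer(fix[i, "POS"]),
    ref = ref[keep],
    alt = alt[keep],
    id = ifelse(is.na(fix[i, "ID"]), ".", fix[i, "ID"]),
    qual = ifelse(is.na(fix[i, "QUAL"]), ".", fix[i, "QUAL"]),
    filter = ifelse(is.na(fix[i, "FILTER"]), ".", fix[i, "FILTER"]),
    info = ifelse(is.na(fix[i, "INFO"]), ".", fix[i, "INFO"]),
    meta = v@meta
  )
  attr(out, "skip_log") <- skip
  out
}

## INFO declarations for the keys this suite may add.
favr_info_declarations <- c(
  FAVR_BIN = '##INFO=<ID=FAVR_BIN,Number=1,Type=String,Description="Reason this variant was binned by a FAVR filter">',
  FAVR_CMP_PCT = '##INFO=<ID=FAVR_CMP_PCT,Number=1,Type=Float,Description="Percent of comparator alignment files that are variant-like at this site">',
  FAVR_PE = '##INFO=<ID=FAVR_PE,Number=1,Type=String,Description="PE bias detector audit flag">',
  FAVR_FAM = '##INFO=<ID=FAVR_FAM,Number=.,Type=String,Description="Per-relative read evidence as sample:alt_count/depth">',
  FAVR_FAM_N = '##INFO=<ID=FAVR_FAM_N,Number=1,Type=Integer,Description="Number of relatives with read evidence for this variant">'
)

#' Write candidate SNV calls to a VCF file
#'
#' Serialises a [snv_calls()] table as a sites-only VCF v4.2 file.  Header
#' lines carried on the object (attribute `"meta"`) are preserved; any
#' `##FAVR_*` provenance lines supplied via `extra_header` are appended, and
#' `##INFO` declarations for FAVR annotation keys present in the records are
#' added when missing.  A `.gz` destination is written gzip-compressed.
#'
#' @param x A [snv_calls()] data frame.
#' @param path Destination path (use a `.gz` suffix for compressed output).
#' @param extra_header Extra `##`-prefixed header lines (e.g. provenance).
#' @return Invisibly, `path`.
#' @seealso [read_snv_calls()]
#' @export
write_snv_calls <- function(x, path, extra_header = character()) {
  x <- as_snv_calls(x)
  meta <- attr(x, "meta") %||% character()
  if (!any(grepl("^##fileformat=", meta)))
    meta <- c("##fileformat=VCFv4.2", meta)
  for (key in names(favr_info_declarations)) {
    used <- any(grepl(paste0("(^|;)", key, "="), x$info)) ||
      (key == "FAVR_PE" && any(grepl("(^|;)FAVR_PE(;|$)", x$info)))
    declared <- any(grepl(paste0("^##INFO=<ID=", key, ","), meta))
    if (used && !declared)
      meta <- c(meta, unname(favr_info_declarations[key]))
  }
  meta <- c(meta, extra_header)
  header_cols <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO"), collapse = "\t")
  body <- if (nrow(x)) {
    paste(x$chrom, x$pos, x$id, x$ref, x$alt, x$qual, x$filter, x$info,
          sep = "\t")
  } else character()
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(c(meta, header_cols, body), con)
  invisible(path)
}

## Add (or replace) key=value inside a VCF INFO string; "." means empty.
info_add <- function(info, key, value) {
  info <- info_drop(info, key)
  entry <- paste0(key, "=", value)
  ifelse(info == "." | info == "", entry, paste0(info, ";", entry))
}

info_drop <- function(info, keys) {
  for (key in keys) {
    pat <- paste0("(^|;)", key, "(=[^;]*)?(;|$)")
    info <- gsub(pat, "\\1", info)
  }
  info <- gsub(";+", ";", info)
  info <- sub(";$", "", sub("^;", "", info))
  ifelse(info == "", ".", info)
}

info_get <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(?<=^|;)", key, "=[^;]*"), info,
                                perl = TRUE))
  out <- rep(NA_character_, length(info))
  hit <- grepl(paste0("(^|;)", key, "="), info)
  out[hit] <- sub(paste0("^", key, "="), "", m)
  out
}

## Standard ##FAVR_* provenance header lines for output VCFs.
favr_provenance <- function(tool, params = list(), files = character()) {
  lines <- c(
    paste0("##FAVR_tool=", tool),
    paste0("##FAVR_version=", favr_version())
  )
  if (length(params)) {
    kv <- paste(names(params), unlist(lapply(params, paste, collapse = ",")),
                sep = "=", collapse = ";")
    lines <- c(lines, paste0("##FAVR_params=", kv))
  }
  if (length(files))
    lines <- c(lines, paste0("##FAVR_files=", paste(files, collapse = ",")))
  lines
}
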