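## Partition of an input variant list into kept and binned, with per-variant
## provenance.  Binned variants are never dropped: they carry a FAVR_BIN
## reason tag and can be written to a sibling VCF.
favr_outcome <- function(kept, binned, provenance, tool, params = list(),
                         files = character()) {
  structure(list(kept = kept, binned = binned, provenance = provenance,
                 tool = tool, params = params, files = files),
            class = "favr_outcome")
}

#' @export
print.favr_outcome <- function(x, ...) {
  n <- nrow(x$kept) + nrow(x$binned)
  cat("<favr_outcome> ", x$tool, "\n", sep = "")
  cat("  input:  ", n, " variant(s)\n", sep = "")
  cat("  kept:   ", nrow(x$kept), "\n", sep = "")
  cat("  binned: ", nrow(x$binned), "\n", sep = "")
  if (length(x$params)) {
    kv <- paste(names(x$params), sapply(x$params, paste, collapse = ","),
                sep = "=", collapse = ", ")
    cat("  params: ", kv, "\n", sep = "")
  }
  invisible(x)
}

#' Write a filter outcome to kept and binned VCF files
#'
#' Both outputs carry `##FAVR_*` provenance header lines recording the tool,
#' package version, parameters and any alignment files consulted; binned
#' records carry their reason in the `FAVR_BIN` INFO key.
#'
#' @param outcome A `favr_outcome` as returned by the filters.
#' @param kept_path,binned_path Destination VCF paths (`binned_path` may be
#'   `NULL` to skip writing the binned set).
#' @return Invisibly, the outcome.
#' @export
write_outcome <- function(outcome, kept_path, binned_path = NULL) {
  stopifnot(inherits(outcome, "favr_outcome"))
  hdr <- favr_provenance(outcome$tool, outcome$params, outcome$files)
  write_snv_calls(outcome$kept, kept_path, extra_header = hdr)
  if (!is.null(binned_path))
    write_snv_calls(outcome$binned, binned_path, extra_header = hdr)
  invisible(outcome)
}
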