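#' Configuration for the synthetic cohort generator
#'
#' Describes a seeded, self-contained cohort: a random reference sequence,
#' per-sample paired-end alignments at a target coverage, and a plan of
#' planted variant sites in five classes mirroring the signal structure of
#' real rare-variant screens:
#' \describe{
#'   \item{`true_rare`}{heterozygous rare variants private to one carrier
#'     (alt fraction ~0.5).  With cousin pairs, each pair member receives
#'     `n_true_rare` sites and each is shared with the other cousin with
#'     probability `kinship` (0.125 for first cousins); without cousin pairs
#'     all sites belong to sample 1, the test sample.}
#'   \item{`shared_family`}{sites carried by both members of a pair (or by
#'     samples 1 and 2), for exercising family annotation; the second
#'     carrier's alt fraction is drawn from `shared_family_fraction`, which
#'     can be set low to emulate a variant a rigid caller misses.}
#'   \item{`common`}{variants planted at heterozygous fractions
#'     (`common_fraction`) in a `common_prevalence` share of samples.}
#'   \item{`artefact_mapping`}{systematic mapping artefacts: sub-homozygous
#'     alt fractions (`artefact_fraction`, bounded below 0.5 by default —
#'     recurrent artefact signals are never homozygous) in an
#'     `artefact_prevalence` share of samples.}
#'   \item{`artefact_pe`}{artefacts whose alt support is confined to the
#'     short mate of imbalanced pairs; always planted in sample 1 (plus a
#'     prevalence-drawn set of other samples).}
#' }
#' Reads are ungapped perfect-match alignments (all-`M` CIGAR) so that
#' pileup semantics rather than alignment are under test;
#' `deletion_read_rate` optionally gives reads a small internal deletion to
#' exercise the rule that a gapped base is no observation.  Randomness is
#' drawn from streams keyed by (seed, stage, site, sample), so enlarging the
#' cohort does not reshuffle earlier samples' reads.
#'
#' @param seed Integer master seed.
#' @param n_samples Number of samples (`S01`, `S02`, ...).
#' @param n_cousin_pairs Number of cousin pairs occupying the first
#'   `2 * n_cousin_pairs` samples.
#' @param reference_length Reference length in bases.
#' @param chrom Reference sequence name.
#' @param mean_coverage Target mean fold-coverage per sample.
#' @param read_length_long,read_length_short Mate lengths in bases (defaults
#'   50/35, an imbalanced SOLiD-style chemistry).
#' @param balanced_pairs If `TRUE`, both mates have `read_length_long`.
#' @param fragment_length Outer fragment span in bases.
#' @param base_error_rate Per-base substitution error probability.
#' @param deletion_read_rate Fraction of reads carrying a 2-base internal
#'   deletion.
#' @param kinship Probability a cousin's rare variant is shared (0.125).
#' @param n_true_rare,n_shared_family,n_common,n_artefact_mapping,n_artefact_pe
#'   Site counts per class (see above for the per-pair semantics of
#'   `n_true_rare`).
#' @param rare_fraction Planted alt fraction for rare/proband sites.
#' @param shared_family_fraction,common_fraction,artefact_fraction Ranges
#'   (length-2 vectors) for per-carrier alt fractions.
#' @param common_prevalence,artefact_prevalence Ranges for the fraction of
#'   samples carrying each common/artefact site.
#' @param call_min_reads,call_min_fraction Candidate-calling rule applied
#'   when emitting per-sample VCFs: a site is called when its alt read count
#'   reaches `call_min_reads` and its alt fraction reaches
#'   `call_min_fraction` (defaults 1 and 0 — permissive, any alt read).
#' @return A `favr_sim_config` list.
#' @export
simulation_config <- function(seed = 1L, n_samples = 10L, n_cousin_pairs = 0L,
                              reference_length = 20000L, chrom = "chrSim",
                              mean_coverage = 30,
                              read_length_long = 50L, read_length_short = 35L,
                              balanced_pairs = FALSE, fragment_length = 150L,
                              base_error_rate = 0, deletion_read_rate = 0,
                              kinship = 0.125,
                              n_true_rare = 30L, n_shared_family = 0L,
                              n_common = 0L, n_artefact_mapping = 0L,
                              n_artefact_pe = 0L,
                              rare_fraction = 0.5,
                              shared_family_fraction = c(0.45, 0.55),
                              common_fraction = c(0.4, 0.6),
                              common_prevalence = c(0.4, 0.8),
                              artefact_fraction = c(0.1, 0.4),
                              artefact_prevalence = c(0.5, 0.9),
                              call_min_reads = 1L, call_min_fraction = 0) {
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              n_cousin_pairs = as.integer(n_cousin_pairs),
              reference_length = as.integer(reference_length), chrom = chrom,
              mean_coverage = mean_coverage,
              read_length_long = as.integer(read_length_long),
              read_length_short = as.integer(read_length_short),
              balanced_pairs = isTRUE(balanced_pairs),
              fragment_length = as.integer(fragment_length),
              base_error_rate = base_error_rate,
              deletion_read_rate = deletion_read_rate,
              kinship = kinship,
              n_true_rare = as.integer(n_true_rare),
              n_shared_family = as.integer(n_shared_family),
              n_common = as.integer(n_common),
              n_artefact_mapping = as.integer(n_artefact_mapping),
              n_artefact_pe = as.integer(n_artefact_pe),
              rare_fraction = rare_fraction,
              shared_family_fraction = shared_family_fraction,
              common_fraction = common_fraction,
              common_prevalence = common_prevalence,
              artefact_fraction = artefact_fraction,
              artefact_prevalence = artefact_prevalence,
              call_min_reads = as.integer(call_min_reads),
              call_min_fraction = call_min_fraction)
  validate_sim_config(cfg)
  structure(cfg, class = "favr_sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_samples >= 1L, cfg$n_cousin_pairs >= 0L,
            2L * cfg$n_cousin_pairs <= cfg$n_samples,
            cfg$mean_coverage > 0,
            cfg$read_length_long >= 20L, cfg$read_length_short >= 20L,
            cfg$read_length_short <= cfg$read_length_long,
            cfg$base_error_rate >= 0, cfg$base_error_rate <= 1,
            cfg$deletion_read_rate >= 0, cfg$deletion_read_rate <= 1,
            cfg$kinship > 0, cfg$kinship <= 1,
            cfg$n_true_rare >= 0L, cfg$n_shared_family >= 0L,
            cfg$n_common >= 0L, cfg$n_artefact_mapping >= 0L,
            cfg$n_artefact_pe >= 0L,
            cfg$rare_fraction > 0, cfg$rare_fraction <= 1)
  short_eff <- if (cfg$balanced_pairs) cfg$read_length_long
               else cfg$read_length_short
  if (cfg$fragment_length < cfg$read_length_long + short_eff)
    stop("fragment_length shorter than the two mates combined", call. = FALSE)
  for (rng in list(cfg$shared_family_fraction, cfg$common_fraction,
                   cfg$artefact_fraction, cfg$common_prevalence,
                   cfg$artefact_prevalence))
    stopifnot(length(rng) == 2L, rng[1] > 0, rng[2] <= 1, rng[1] <= rng[2])
  invisible(cfg)
}

## total planted sites for a config (cousin top-up is stochastic; this is the
## worst case used for the feasibility check)
max_sites <- function(cfg) {
  rare <- if (cfg$n_cousin_pairs > 0L)
    2L * cfg$n_cousin_pairs * cfg$n_true_rare else cfg$n_true_rare
  fam_groups <- max(cfg$n_cousin_pairs, 1L)
  rare + fam_groups * cfg$n_shared_family + cfg$n_common +
    cfg$n_artefact_mapping + cfg$n_artefact_pe
}

#' Plant alternate-allele read support at a site
#'
#' Mutates the base at `pos` to `alt` in a chosen subset of the reads that
#' cover the position with an aligned (non-gap) base.  The number of mutated
#' reads is the nearest integer to `target_fraction` times the eligible
#' depth (at least `min_reads` when the target is positive).  With
#' `restrict = "short-mate"` only short-mate (second-of-pair) reads are
#' mutated; with no restriction and `balance = TRUE` at least one long-mate
#' read is included whenever one covers the site, so genuine planted
#' variants always have mate-balanced support.
#'
#' @param reads A read table as built by [simulate_cohort()] (columns
#'   `start`, `ref_end`, `cigar`, `seq`, `flag`).
#' @param pos,alt Site position and alternate base.
#' @param target_fraction Target alt read fraction in `[0, 1]`.
#' @param restrict `"none"` or `"short-mate"`.
#' @param min_reads Minimum planted reads when `target_fraction > 0`
#'   (default 1, so designated carriers are never empty by rounding).
#' @param balance Guarantee a long-mate alt read when possible (ignored when
#'   restricted).
#' @return A list: `reads` (mutated table), `planted` (reads mutated),
#'   `depth` (eligible depth), `achieved_fraction`, and `feasible` (`FALSE`
#'   when the restriction or coverage makes planting impossible, in which
#'   case `reads` is returned unchanged).
#' @export
plant_read_support <- function(reads, pos, alt, target_fraction,
                               restrict = c("none", "short-mate"),
                               min_reads = 1L, balance = TRUE) {
  restrict <- match.arg(restrict)
  stopifnot(target_fraction >= 0, target_fraction <= 1)
  ov <- which(reads$start <= pos & reads$ref_end >= pos)
  off <- read_offsets(reads, ov, pos)
  elig <- ov[!is.na(off) & off >= 1L]
  off <- off[!is.na(off) & off >= 1L]
  depth <- length(elig)
  if (target_fraction == 0)
    return(list(reads = reads, planted = 0L, depth = depth,
                achieved_fraction = 0, feasible = TRUE))
  if (depth == 0L)
    return(list(reads = reads, planted = 0L, depth = 0L,
                achieved_fraction = NA_real_, feasible = FALSE))
  n_alt <- max(min_reads, round_half_up(target_fraction * depth))
  n_alt <- min(n_alt, depth)
  is_short <- bitwAnd(reads$flag[elig], 128L) > 0L
  if (restrict == "short-mate") {
    pool <- which(is_short)
    if (length(pool) == 0L)
      return(list(reads = reads, planted = 0L, depth = depth,
                  achieved_fraction = NA_real_, feasible = FALSE))
    n_alt <- min(n_alt, length(pool))
    sel <- pool[sample.int(length(pool), n_alt)]
  } else {
    sel <- sample.int(depth, n_alt)
    if (balance && !any(!is_short[sel]) && any(!is_short)) {
      longs <- which(!is_short)
      sel[1] <- longs[sample.int(length(longs), 1L)]
      sel <- unique(sel)
    }
  }
  for (k in sel)
    substr(reads$seq[elig[k]], off[k], off[k]) <- alt
  list(reads = reads, planted = length(sel), depth = depth,
       achieved_fraction = length(sel) / depth, feasible = TRUE)
}

## Query offsets for the reads indexed by `ov` at `pos`.  Reads whose CIGAR
## is a single match run take the arithmetic fast path; others are walked
## via the op/len list-columns attached by generate_sample_reads() (or
## parsed on the fly for externally built read tables).
read_offsets <- function(reads, ov, pos) {
  n <- length(ov)
  off <- integer(n)
  if (n == 0L) return(off)
  simple <- if ("simple" %in% names(reads)) reads$simple[ov]
            else grepl("^[0-9]+M$", reads$cigar[ov])
  off[simple] <- pos - reads$start[ov[simple]] + 1L
  has_cache <- "cigar_ops" %in% names(reads)
  for (k in which(!simple)) {
    r <- ov[k]
    if (has_cache && !is.null(reads$cigar_ops[[r]])) {
      ops <- reads$cigar_ops[[r]]
      lens <- reads$cigar_lens[[r]]
    } else {
      lens <- as.integer(regmatches(reads$cigar[r],
                                    gregexpr("[0-9]+", reads$cigar[r]))[[1]])
      ops <- regmatches(reads$cigar[r],
                        gregexpr("[MIDNSHP=X]", reads$cigar[r]))[[1]]
    }
    off[k] <- query_offset(ops, lens, reads$start[r], pos)
  }
  off
}

## non-mutating eligible-depth summary used for feasibility / counting
site_support <- function(reads, pos, alt) {
  ov <- which(reads$start <= pos & reads$ref_end >= pos)
  if (length(ov) == 0L)
    return(list(depth = 0L, alt_count = 0L, n_short = 0L))
  off <- read_offsets(reads, ov, pos)
  use <- !is.na(off) & off >= 1L
  ov <- ov[use]; off <- off[use]
  if (length(ov) == 0L)
    return(list(depth = 0L, alt_count = 0L, n_short = 0L))
  base <- substr(reads$seq[ov], off, off)
  list(depth = length(ov), alt_count = sum(base == alt),
       n_short = sum(bitwAnd(reads$flag[ov], 128L) > 0L))
}

generate_sample_reads <- function(cfg, sample_i, ref_chars) {
  L <- cfg$reference_length
  len_long <- cfg$read_length_long
  len_short <- if (cfg$balanced_pairs) cfg$read_length_long
               else cfg$read_length_short
  flen <- cfg$fragment_length
  with_seed(derive_seed(cfg$seed, "reads", sample_i), {
    n_frag <- max(1L, round_half_up(cfg$mean_coverage * L /
                                      (len_long + len_short)))
    starts <- sample.int(L - flen + 1L, n_frag, replace = TRUE)
    qname <- sprintf("S%02d_f%06d", sample_i, seq_len(n_frag))
    s_start <- starts + flen - len_short
    reads <- data.frame(
      qname = c(qname, qname),
      flag = c(rep(99L, n_frag), rep(147L, n_frag)),
      start = c(starts, s_start),
      len = c(rep(len_long, n_frag), rep(len_short, n_frag)),
      mpos = c(s_start, starts),
      tlen = c(rep(flen, n_frag), rep(-flen, n_frag)),
      stringsAsFactors = FALSE
    )
    reads$cigar <- paste0(reads$len, "M")
    reads$ref_end <- reads$start + reads$len - 1L
    n <- nrow(reads)
    reads$simple <- rep(TRUE, n)
    del <- integer(0)
    if (cfg$deletion_read_rate > 0) {
      del <- which(stats::runif(n) < cfg$deletion_read_rate &
                     reads$start + reads$len + 1L <= L)
      if (length(del)) {
        h <- reads$len[del] %/% 2L
        reads$cigar[del] <- paste0(h, "M2D", reads$len[del] - h, "M")
        reads$ref_end[del] <- reads$start[del] + reads$len[del] + 1L
        reads$simple[del] <- FALSE
      }
    }
    # sequences from the reference, skipping any deleted bases
    ref_str <- attr(ref_chars, "ref_str")
    reads$seq <- substring(ref_str, reads$start, reads$start + reads$len - 1L)
    if (length(del)) {
      h <- reads$len[del] %/% 2L
      reads$seq[del] <- paste0(
        substring(ref_str, reads$start[del], reads$start[del] + h - 1L),
        substring(ref_str, reads$start[del] + h + 2L,
                  reads$start[del] + reads$len[del] + 1L))
    }
    reads$cigar_ops <- vector("list", n)
    reads$cigar_lens <- vector("list", n)
    for (r in del) {
      h <- reads$len[r] %/% 2L
      reads$cigar_ops[[r]] <- c("M", "D", "M")
      reads$cigar_lens[[r]] <- c(h, 2L, reads$len[r] - h)
    }
    if (cfg$base_error_rate > 0) {
      nerr <- stats::rbinom(n, reads$len, cfg$base_error_rate)
      bases <- c("A", "C", "G", "T")
      for (r in which(nerr > 0L)) {
        offs <- sample.int(reads$len[r], nerr[r])
        for (o in offs) {
          cur <- substr(reads$seq[r], o, o)
          substr(reads$seq[r], o, o) <- sample(setdiff(bases, cur), 1L)
        }
      }
    }
    reads[order(reads$start, reads$qname, reads$flag), , drop = FALSE]
  })
}

build_site_plan <- function(cfg, positions) {
  n_samples <- cfg$n_samples
  pairs <- if (cfg$n_cousin_pairs > 0L)
    lapply(seq_len(cfg$n_cousin_pairs), function(p) c(2L * p - 1L, 2L * p))
  else list()
  add <- function(acc, class, carriers, fractions, restricted = FALSE) {
    acc[[length(acc) + 1L]] <- list(class = class, carriers = carriers,
                                    fractions = fractions,
                                    restricted = restricted)
    acc
  }
  sites <- list()
  # private rare variants, with cousin sharing
  if (cfg$n_true_rare > 0L) {
    if (length(pairs)) {
      for (pr in pairs) {
        shared <- stats::runif(cfg$n_true_rare) < cfg$kinship
        for (k in seq_len(cfg$n_true_rare)) {
          carriers <- if (shared[k]) pr else pr[1]
          sites <- add(sites, "true_rare", carriers,
                       rep(cfg$rare_fraction, length(carriers)))
        }
        for (k in seq_len(cfg$n_true_rare - sum(shared)))
          sites <- add(sites, "true_rare", pr[2], cfg$rare_fraction)
      }
    } else {
      for (k in seq_len(cfg$n_true_rare))
        sites <- add(sites, "true_rare", 1L, cfg$rare_fraction)
    }
  }
  if (cfg$n_shared_family > 0L) {
    groups <- if (length(pairs)) pairs else list(c(1L, min(2L, n_samples)))
    for (g in groups) {
      g <- unique(g)
      for (k in seq_len(cfg$n_shared_family)) {
        fr <- c(cfg$rare_fraction,
                stats::runif(length(g) - 1L, cfg$shared_family_fraction[1],
                             cfg$shared_family_fraction[2]))
        sites <- add(sites, "shared_family", g, fr[seq_along(g)])
      }
    }
  }
  if (cfg$n_common > 0L) {
    for (k in seq_len(cfg$n_common)) {
      q <- stats::runif(1, cfg$common_prevalence[1], cfg$common_prevalence[2])
      nc <- max(1L, round_half_up(q * n_samples))
      carriers <- sort(sample.int(n_samples, min(nc, n_samples)))
      sites <- add(sites, "common", carriers,
                   stats::runif(length(carriers), cfg$common_fraction[1],
                                cfg$common_fraction[2]))
    }
  }
  if (cfg$n_artefact_mapping > 0L) {
    for (k in seq_len(cfg$n_artefact_mapping)) {
      q <- stats::runif(1, cfg$artefact_prevalence[1],
                        cfg$artefact_prevalence[2])
      nc <- max(1L, round_half_up(q * n_samples))
      carriers <- sort(sample.int(n_samples, min(nc, n_samples)))
      sites <- add(sites, "artefact_mapping", carriers,
                   stats::runif(length(carriers), cfg$artefact_fraction[1],
                                cfg$artefact_fraction[2]))
    }
  }
  if (cfg$n_artefact_pe > 0L) {
    for (k in seq_len(cfg$n_artefact_pe)) {
      q <- stats::runif(1, cfg$artefact_prevalence[1],
                        cfg$artefact_prevalence[2])
      nc <- max(1L, round_half_up(q * n_samples))
      carriers <- sort(unique(c(1L, sample.int(n_samples,
                                               min(nc, n_samples)))))
      sites <- add(sites, "artefact_pe", carriers,
                   stats::runif(length(carriers), cfg$artefact_fraction[1],
                                cfg$artefact_fraction[2]),
                   restricted = TRUE)
    }
  }
  sites
}

#' Generate a seeded synthetic cohort
#'
#' Produces, under `dir`: a reference FASTA (`reference.fasta`, with `.fai`
#' index), per-sample coordinate-sorted and indexed BAM files (`SXX.bam`,
#' with the plain-text SAM they were built from), per-sample candidate VCFs
#' (`SXX.candidates.vcf`, every planted site with read support meeting the
#' permissive calling rule in the config), a site-level ground-truth table
#' (`truth.tsv`), a per-(site, carrier) planting table
#' (`truth_plants.tsv`) and the configuration (`sim_config.json`).  Output
#' is byte-reproducible for a given configuration.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return A `favr_cohort` list: `samples` (data frame of ids and file
#'   paths), `sites`, `plants`, `calls` (named list of [snv_calls()] tables),
#'   `chrom`, `reference`, `dir` and `config`.
#' @export
simulate_cohort <- function(config, dir) {
  stopifnot(inherits(config, "favr_sim_config"))
  cfg <- config
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  L <- cfg$reference_length
  margin <- 2L * cfg$fragment_length
  usable <- seq.int(margin + 1L, L - margin)
  reserve <- 50L
  need <- max_sites(cfg)
  if (need + reserve > length(usable))
    stop("infeasible site plan: ", need, " sites will not fit on a ",
         L, "-base reference", call. = FALSE)

  ref_chars <- with_seed(derive_seed(cfg$seed, "reference"),
                         sample(c("A", "C", "G", "T"), L, replace = TRUE))
  attr(ref_chars, "ref_str") <- paste(ref_chars, collapse = "")

  plan <- with_seed(derive_seed(cfg$seed, "plan"), {
    sites <- build_site_plan(cfg, NULL)
    pos_pool <- sample(usable, length(sites) + reserve)
    list(sites = sites, pos_pool = pos_pool,
         alts = vapply(seq_along(sites), function(i) {
           sample(setdiff(c("A", "C", "G", "T"),
                          ref_chars[pos_pool[i]]), 1L)
         }, ""))
  })
  sites <- plan$sites
  n_sites <- length(sites)
  for (i in seq_len(n_sites)) {
    sites[[i]]$pos <- plan$pos_pool[i]
    sites[[i]]$alt <- plan$alts[i]
    sites[[i]]$relocated <- FALSE
  }
  reserve_pos <- plan$pos_pool[seq.int(n_sites + 1L, length(plan$pos_pool))]

  # order sites along the reference; the post-sort index keys plant streams
  ord <- order(vapply(sites, `[[`, 0L, "pos"))
  sites <- sites[ord]

  sample_ids <- sprintf("S%02d", seq_len(cfg$n_samples))
  reads <- lapply(seq_len(cfg$n_samples), function(i)
    generate_sample_reads(cfg, i, ref_chars))

  # feasibility pass: relocate sites whose restriction cannot be honoured
  # (e.g. no short-mate read covers the position in some carrier)
  reserve_used <- 0L
  for (s in seq_len(n_sites)) {
    repeat {
      ok <- TRUE
      for (ci in seq_along(sites[[s]]$carriers)) {
        smp <- sites[[s]]$carriers[ci]
        sup <- site_support(reads[[smp]], sites[[s]]$pos, sites[[s]]$alt)
        if (sup$depth == 0L ||
            (sites[[s]]$restricted && sup$n_short == 0L)) {
          ok <- FALSE
          break
        }
      }
      if (ok) break
      reserve_used <- reserve_used + 1L
      if (reserve_used > length(reserve_pos))
        stop("could not place all sites: coverage too sparse", call. = FALSE)
      message("relocating site ", s, " (class ", sites[[s]]$class,
              "): planting constraint unsatisfiable at position ",
              sites[[s]]$pos)
      sites[[s]]$pos <- reserve_pos[reserve_used]
      sites[[s]]$alt <- with_seed(
        derive_seed(cfg$seed, "relocate", s, reserve_used),
        sample(setdiff(c("A", "C", "G", "T"),
                       ref_chars[sites[[s]]$pos]), 1L))
      sites[[s]]$relocated <- TRUE
    }
  }

  # planting pass
  plants <- list()
  for (smp in seq_len(cfg$n_samples)) {
    for (s in seq_len(n_sites)) {
      ci <- match(smp, sites[[s]]$carriers)
      if (is.na(ci)) next
      res <- with_seed(derive_seed(cfg$seed, "plant", s, smp),
        plant_read_support(reads[[smp]], sites[[s]]$pos, sites[[s]]$alt,
                           target_fraction = sites[[s]]$fractions[ci],
                           restrict = if (sites[[s]]$restricted)
                             "short-mate" else "none"))
      if (!res$feasible)
        stop("internal: infeasible plant after relocation pass",
             call. = FALSE)
      reads[[smp]] <- res$reads
      plants[[length(plants) + 1L]] <- data.frame(
        site_index = s, sample_id = sample_ids[smp],
        class = sites[[s]]$class,
        target_fraction = sites[[s]]$fractions[ci],
        planted_alt = res$planted, eligible_depth = res$depth,
        achieved_fraction = res$achieved_fraction,
        stringsAsFactors = FALSE)
    }
  }
  plants <- do.call(rbind, c(plants, list(data.frame())))

  # reference FASTA + index
  ref_path <- file.path(dir, "reference.fasta")
  ref_set <- Biostrings::DNAStringSet(attr(ref_chars, "ref_str"))
  names(ref_set) <- cfg$chrom
  Biostrings::writeXStringSet(ref_set, ref_path)
  Rsamtools::indexFa(ref_path)

  site_pos <- vapply(sites, `[[`, 0L, "pos")
  site_alt <- vapply(sites, `[[`, "", "alt")
  site_ref <- ref_chars[site_pos]
  site_ids <- sprintf("site%04d", seq_len(n_sites))

  # per-sample outputs
  samples <- data.frame(sample_id = sample_ids,
                        bam = file.path(dir, paste0(sample_ids, ".bam")),
                        sam = file.path(dir, paste0(sample_ids, ".sam")),
                        vcf = file.path(dir,
                                        paste0(sample_ids, ".candidates.vcf")),
                        stringsAsFactors = FALSE)
  calls <- vector("list", cfg$n_samples)
  names(calls) <- sample_ids
  counts_all <- vector("list", cfg$n_samples)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", cfg$chrom, "\tLN:", L))
  for (smp in seq_len(cfg$n_samples)) {
    rd <- reads[[smp]]
    lines <- paste(rd$qname, rd$flag, cfg$chrom, rd$start, 60L, rd$cigar,
                   "=", rd$mpos, rd$tlen, rd$seq, strrep("I", rd$len),
                   sep = "\t")
    writeLines(c(header, lines), samples$sam[smp])
    Rsamtools::asBam(samples$sam[smp],
                     sub("\\.bam$", "", samples$bam[smp]),
                     overwrite = TRUE, indexDestination = TRUE)
    cnt <- data.frame(site_index = seq_len(n_sites), depth = 0L,
                      alt_count = 0L)
    for (s in seq_len(n_sites)) {
      sup <- site_support(rd, site_pos[s], site_alt[s])
      cnt$depth[s] <- sup$depth
      cnt$alt_count[s] <- sup$alt_count
    }
    counts_all[[smp]] <- cnt
    called <- cnt$alt_count >= cfg$call_min_reads & cnt$depth > 0L &
      (cnt$alt_count >= cfg$call_min_fraction * cnt$depth)
    sn <- if (any(called)) {
      snv_calls(chrom = cfg$chrom, pos = site_pos[called],
                ref = site_ref[called], alt = site_alt[called],
                id = site_ids[called],
                info = paste0("DP=", cnt$depth[called]))
    } else empty_snv_calls()
    calls[[smp]] <- sn
    write_snv_calls(sn, samples$vcf[smp],
                    extra_header = favr_provenance(
                      "simulate", params = list(seed = cfg$seed,
                                                sample = sample_ids[smp])))
  }

  sites_df <- data.frame(
    site_id = site_ids,
    class = vapply(sites, `[[`, "", "class"),
    chrom = cfg$chrom, pos = site_pos, ref = site_ref, alt = site_alt,
    carriers = vapply(sites, function(s)
      paste(sample_ids[s$carriers], collapse = ","), ""),
    n_carriers = vapply(sites, function(s) length(s$carriers), 0L),
    mate_restricted = vapply(sites, `[[`, FALSE, "restricted"),
    relocated = vapply(sites, `[[`, FALSE, "relocated"),
    stringsAsFactors = FALSE)
  if (nrow(plants)) {
    plants$site_id <- site_ids[plants$site_index]
    idx <- match(paste(plants$site_index, plants$sample_id),
                 paste(rep(seq_len(n_sites), cfg$n_samples),
                       rep(sample_ids, each = n_sites)))
    all_counts <- do.call(rbind, counts_all)
    plants$alt_count <- all_counts$alt_count[idx]
    plants$depth <- all_counts$depth[idx]
    plants <- plants[, c("site_id", "class", "sample_id", "target_fraction",
                         "planted_alt", "eligible_depth",
                         "achieved_fraction", "alt_count", "depth")]
  }
  utils::write.table(sites_df, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(plants, file.path(dir, "truth_plants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(cfg), file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(list(dir = dir, chrom = cfg$chrom, reference = ref_path,
                 samples = samples, sites = sites_df, plants = plants,
                 calls = calls, config = cfg),
            class = "favr_cohort")
}

#' @export
print.favr_cohort <- function(x, ...) {
  cat("<favr_cohort> ", nrow(x$samples), " sample(s), ", nrow(x$sites),
      " planted site(s) in ", x$dir, "\n", sep = "")
  if (nrow(x$sites))
    print(table(x$sites$class))
  invisible(x)
}
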