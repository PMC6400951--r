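#' Junction filter configuration
#'
#' Thresholds of the junction quality/size/genic-region filter:
#' junctions need at least `min_support` supporting fragments, or at least
#' `rescue_support` of their own when the same junction is present with
#' `min_support` in a related sample of the patient; intrachromosomal
#' junctions must be larger than `min_intra_size` to exclude common small
#' polymorphisms, and those between `min_intra_size` and `genic_check_max`
#' are kept only when a breakpoint falls in a gene region; junctions from
#' different samples are identified when both breakpoint distances are within
#' `match_tolerance`.
#'
#' @param min_support quality threshold on supporting fragments (default 7).
#' @param rescue_support cross-sample rescue floor (default 3).
#' @param min_intra_size minimal intrachromosomal junction size in bp
#'   (default 50 kb, exclusive: junctions must be strictly larger).
#' @param genic_check_max upper bound of the genic-region check range in bp
#'   (default 100 kb, inclusive).
#' @param match_tolerance per-breakpoint matching tolerance in bp (default
#'   10 kb, inclusive).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_support = 7, rescue_support = 3,
                          min_intra_size = 5e4, genic_check_max = 1e5,
                          match_tolerance = 1e4) {
  cfg <- as.list(environment())
  if (any(unlist(cfg) <= 0)) stop_input("all filter thresholds must be > 0")
  if (rescue_support > min_support)
    stop_input("rescue_support must be <= min_support")
  if (min_intra_size > genic_check_max)
    stop_input("min_intra_size must be <= genic_check_max")
  class(cfg) <- "filter_config"
  cfg
}

#' Apply quality, rescue and size/genic filters to one sample
#'
#' Retains a junction when its support reaches `min_support`, or when it has
#' at least `rescue_support` of its own and matches (within
#' `match_tolerance`, via [match_junctions()]) a junction with support
#' `>= min_support` in a related sample of the same patient. Surviving
#' intrachromosomal junctions are then size-filtered: those of at most
#' `min_intra_size` are removed; those between `min_intra_size` and
#' `genic_check_max` are kept only when either breakpoint overlaps a gene
#' region; larger ones, and all interchromosomal junctions, are exempt.
#'
#' @param sample a [call_set()].
#' @param related_samples list of [call_set()]s from the same patient
#'   (pre-filter call sets; used for rescue only).
#' @param config a [filter_config()].
#' @param genome a [genome_model()] supplying gene regions.
#' @return The filtered [call_set()]; a per-junction report data.frame
#'   (`id`, `rule`, `kept`) is attached as attribute `"filter_report"`.
#' @export
filter_sample <- function(sample, related_samples = list(),
                          config = filter_config(), genome) {
  stopifnot(inherits(sample, "call_set"), inherits(config, "filter_config"))
  for (r in related_samples) {
    if (!identical(r$patient_id, sample$patient_id))
      stop_input("related sample ", r$sample_id, " is from a different patient")
  }
  j <- sample$junctions
  n <- nrow(j)
  if (!n) {
    attr(sample, "filter_report") <-
      data.frame(id = character(), rule = character(), kept = logical())
    return(sample)
  }
  rule <- rep("pass", n)

  ## support / cross-sample rescue
  high <- j$support >= config$min_support
  rescued <- rep(FALSE, n)
  cand <- which(!high & j$support >= config$rescue_support)
  if (length(cand) && length(related_samples)) {
    pool <- do.call(rbind, lapply(related_samples, function(r) {
      rj <- r$junctions
      rj[rj$support >= config$min_support, , drop = FALSE]
    }))
    if (!is.null(pool) && nrow(pool)) {
      mm <- junction_match_matrix(j[cand, , drop = FALSE], pool,
                                  config$match_tolerance)
      rescued[cand] <- rowSums(mm) > 0
    }
  }
  keep <- high | rescued
  rule[!keep] <- "low_support"

  ## size / genic-region rules (intrachromosomal only)
  intra <- junction_is_intra(j)
  size <- junction_size(j)
  small <- keep & intra & size <= config$min_intra_size
  keep[small] <- FALSE
  rule[small] <- "intra_size"
  mid <- keep & intra & size > config$min_intra_size &
    size <= config$genic_check_max
  if (any(mid)) {
    g1 <- gene_hits(genome, j$chrom1[mid], j$pos1[mid])
    g2 <- gene_hits(genome, j$chrom2[mid], j$pos2[mid])
    nongenic <- is.na(g1) & is.na(g2)
    drop <- which(mid)[nongenic]
    keep[drop] <- FALSE
    rule[drop] <- "nongenic_region"
  }
  rule[keep & rescued] <- "rescued"

  out <- sample
  out$junctions <- as_junction_table(j[keep, , drop = FALSE])
  rownames(out$junctions) <- NULL
  attr(out, "filter_report") <- data.frame(id = j$id, rule = rule, kept = keep)
  out
}

#' Subtract germline junctions using a matched normal
#'
#' Removes from a tumour call set every junction that matches (both
#' breakpoints within `tolerance`) any junction of the patient's normal
#' sample; such junctions are germline events, uninformative for tumour
#' lineage. With no normal sample available (`normal = NULL`) the input is
#' returned unchanged with a warning — the size filters then stand in for
#' germline exclusion.
#'
#' @param tumour,normal [call_set()]s of the same patient (`normal` may be
#'   `NULL`).
#' @param tolerance matching tolerance in bp.
#' @return The tumour [call_set()] with germline-matching junctions removed.
#' @export
subtract_germline <- function(tumour, normal, tolerance = 1e4) {
  stopifnot(inherits(tumour, "call_set"))
  if (is.null(normal)) {
    warning("no normal sample for patient ", tumour$patient_id,
            "; germline junctions not subtracted")
    return(tumour)
  }
  stopifnot(inherits(normal, "call_set"))
  if (!nrow(tumour$junctions) || !nrow(normal$junctions)) return(tumour)
  mm <- junction_match_matrix(tumour$junctions, normal$junctions, tolerance)
  out <- tumour
  out$junctions <- as_junction_table(
    tumour$junctions[rowSums(mm) == 0, , drop = FALSE])
  rownames(out$junctions) <- NULL
  out
}
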