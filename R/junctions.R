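#' Build a junction table
#'
#' A junction is the fused pair of genomic breakpoints created by a
#' chromosomal rearrangement, together with the number of mate-pair fragments
#' supporting it. Junctions are stored one per row and kept in canonical
#' breakpoint order: breakpoint 1 precedes breakpoint 2 lexicographically by
#' chromosome name, then by position; swapping ends carries the strands along.
#'
#' @param chrom1,pos1,strand1 first breakpoint (chromosome, 0-based position,
#'   orientation `"+"`/`"-"`).
#' @param chrom2,pos2,strand2 second breakpoint.
#' @param support integer supporting-fragment counts (>= 1).
#' @param id optional junction identifiers (generated if missing).
#' @param ... further per-junction columns recycled to length.
#'
#' @return data.frame of class `junction_table` with columns `id`, `chrom1`,
#'   `pos1`, `strand1`, `chrom2`, `pos2`, `strand2`, `support` plus any extras.
#' @export
junction_table <- function(chrom1 = character(), pos1 = numeric(),
                           strand1 = character(), chrom2 = character(),
                           pos2 = numeric(), strand2 = character(),
                           support = integer(), id = NULL, ...) {
  n <- length(chrom1)
  if (is.null(id)) id <- if (n) sprintf("J%04d", seq_len(n)) else character()
  j <- data.frame(id = as.character(id),
                  chrom1 = as.character(chrom1), pos1 = as.numeric(pos1),
                  strand1 = as.character(strand1),
                  chrom2 = as.character(chrom2), pos2 = as.numeric(pos2),
                  strand2 = as.character(strand2),
                  support = as.numeric(support),
                  stringsAsFactors = FALSE)
  extra <- list(...)
  for (nmx in names(extra)) j[[nmx]] <- extra[[nmx]]
  if (n && any(j$support < 1)) stop_input("junction support must be >= 1")
  if (n && !all(c(j$strand1, j$strand2) %in% c("+", "-")))
    stop_input("strands must be '+' or '-'")
  j <- canonicalize_junctions(j)
  class(j) <- c("junction_table", "data.frame")
  j
}

## Enforce canonical breakpoint order in place.
canonicalize_junctions <- function(j) {
  if (!nrow(j)) return(j)
  flip <- (j$chrom2 < j$chrom1) |
    (j$chrom2 == j$chrom1 & j$pos2 < j$pos1)
  if (any(flip)) {
    tmp <- j[flip, c("chrom1", "pos1", "strand1")]
    j[flip, c("chrom1", "pos1", "strand1")] <-
      j[flip, c("chrom2", "pos2", "strand2")]
    j[flip, c("chrom2", "pos2", "strand2")] <- tmp
  }
  j
}

empty_junctions <- function() junction_table()

as_junction_table <- function(j) {
  stopifnot(is.data.frame(j))
  j <- canonicalize_junctions(j)
  if (!inherits(j, "junction_table"))
    class(j) <- c("junction_table", "data.frame")
  j
}

#' Is a junction intrachromosomal, and its size
#'
#' Size is defined only for intrachromosomal junctions, as the distance
#' between the two breakpoints; interchromosomal junctions get `NA`.
#'
#' @param junctions a [junction_table()].
#' @return `junction_is_intra`: logical vector; `junction_size`: numeric bp.
#' @export
junction_is_intra <- function(junctions) {
  junctions$chrom1 == junctions$chrom2
}

#' @rdname junction_is_intra
#' @export
junction_size <- function(junctions) {
  ifelse(junction_is_intra(junctions),
         abs(junctions$pos2 - junctions$pos1), NA_real_)
}

#' Do two junctions represent the same rearrangement?
#'
#' Junctions from different samples are considered the same event when both
#' breakpoints agree in chromosome and orientation and each pair of positions
#' differs by at most `tolerance` bp (inclusive).
#'
#' @param a,b single-row [junction_table()]s (canonically ordered).
#' @param tolerance per-breakpoint distance tolerance in bp (default 10 kb).
#' @return TRUE/FALSE.
#' @export
match_junctions <- function(a, b, tolerance = 1e4) {
  stopifnot(nrow(a) == 1L, nrow(b) == 1L)
  a$chrom1 == b$chrom1 && a$chrom2 == b$chrom2 &&
    a$strand1 == b$strand1 && a$strand2 == b$strand2 &&
    abs(a$pos1 - b$pos1) <= tolerance &&
    abs(a$pos2 - b$pos2) <= tolerance
}

## Vectorised all-pairs match: logical matrix nrow(a) x nrow(b).
junction_match_matrix <- function(a, b, tolerance = 1e4) {
  na <- nrow(a); nb <- nrow(b)
  if (!na || !nb) return(matrix(FALSE, na, nb))
  key_a <- paste(a$chrom1, a$strand1, a$chrom2, a$strand2)
  key_b <- paste(b$chrom1, b$strand1, b$chrom2, b$strand2)
  outer(key_a, key_b, "==") &
    abs(outer(a$pos1, b$pos1, "-")) <= tolerance &
    abs(outer(a$pos2, b$pos2, "-")) <= tolerance
}

#' Build a sample call set
#'
#' A call set bundles the junctions of one micro-dissected histologic
#' component with its identifying metadata.
#'
#' @param sample_id,patient_id identifiers.
#' @param histology one of [histology_levels()].
#' @param junctions a [junction_table()].
#' @param is_normal logical; defaults to `histology == "normal"`.
#'
#' @return An object of class `call_set`.
#' @export
call_set <- function(sample_id, patient_id, histology,
                     junctions = empty_junctions(),
                     is_normal = identical(histology, "normal")) {
  if (!histology %in% HISTOLOGIES)
    stop_input("unknown histology label: ", histology)
  structure(list(sample_id = sample_id, patient_id = patient_id,
                 histology = histology, is_normal = isTRUE(is_normal),
                 junctions = as_junction_table(junctions)),
            class = "call_set")
}

#' @export
print.call_set <- function(x, ...) {
  cat(sprintf("call_set %s (patient %s, %s%s): %d junctions\n",
              x$sample_id, x$patient_id, x$histology,
              if (x$is_normal) ", normal" else "", nrow(x$junctions)))
  invisible(x)
}
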