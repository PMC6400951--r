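#' Classify mate-pair fragments as concordant or discordant
#'
#' A fragment is discordant when its ends map to different chromosomes, when
#' its orientations are inconsistent with a properly paired fragment
#' (`+`/`-` with the `+` end upstream), or when its intrachromosomal span
#' exceeds `max(min_event_size, mean + 4*sd)` of the fragment-size model.
#' The 30 kb default floor reflects the convention of reporting only
#' rearrangements larger than 30 kb.
#'
#' @param fragments data.frame with columns `chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2` (canonical end order: end 1 before end 2).
#' @param fragment_size_mean,fragment_size_sd fragment-size model in bp.
#' @param min_event_size minimal event size in bp (default 30000).
#' @return character vector, `"concordant"` or `"discordant"`.
#' @export
classify_fragments <- function(fragments, fragment_size_mean = 3700,
                               fragment_size_sd = 370,
                               min_event_size = 3e4) {
  if (fragment_size_mean <= 0 || fragment_size_sd < 0)
    stop_input("fragment size model must be positive")
  span_max <- max(min_event_size, fragment_size_mean + 4 * fragment_size_sd)
  inter <- fragments$chrom1 != fragments$chrom2
  proper <- fragments$strand1 == "+" & fragments$strand2 == "-"
  span <- abs(fragments$pos2 - fragments$pos1)
  ifelse(inter | !proper | span > span_max, "discordant", "concordant")
}

#' @rdname classify_fragments
#' @param fragment a single-row fragment data.frame.
#' @export
classify_fragment <- function(fragment, fragment_size_mean = 3700,
                              fragment_size_sd = 370, min_event_size = 3e4) {
  classify_fragments(fragment, fragment_size_mean, fragment_size_sd,
                     min_event_size)[1]
}

#' Detect junctions by clustering discordant fragments
#'
#' Discordant fragments are grouped by single-linkage clustering: two
#' fragments link when their corresponding ends lie on identical chromosomes
#' with identical orientations and both positional gaps are at most
#' `cluster_window` bp. Each cluster of at least `min_cluster` fragments is
#' emitted as a junction whose breakpoints are the orientation-aware
#' innermost fragment ends (maximal position on a `+` side, minimal on a
#' `-` side) and whose support is the cluster size.
#'
#' @param fragments fragment data.frame from a single sample (see
#'   [classify_fragments()] for columns; a `sample_id` column, if present,
#'   must be constant).
#' @param cluster_window single-linkage window in bp; default twice the mean
#'   fragment size, the positional uncertainty of a mate-pair library.
#' @param min_cluster minimal cluster size emitted (default 1; quality
#'   filtering happens downstream).
#' @param fragment_size_mean,fragment_size_sd,min_event_size passed to
#'   [classify_fragments()].
#' @return A [junction_table()] sorted by breakpoint coordinates.
#' @export
detect_junctions <- function(fragments, cluster_window = 2 * 3700,
                             min_cluster = 1, fragment_size_mean = 3700,
                             fragment_size_sd = 370, min_event_size = 3e4) {
  if (!is.null(fragments$sample_id) &&
      length(unique(fragments$sample_id)) > 1L)
    stop_input("detect_junctions expects fragments from a single sample")
  fragments <- canonicalize_junctions(fragments)
  disc <- fragments[classify_fragments(fragments, fragment_size_mean,
                                       fragment_size_sd,
                                       min_event_size) == "discordant", ,
                    drop = FALSE]
  n <- nrow(disc)
  if (!n) return(junction_table())
  key <- paste(disc$chrom1, disc$strand1, disc$chrom2, disc$strand2)
  cluster_id <- integer(n)
  n_clusters <- 0
  for (k in unique(key)) {
    idx <- which(key == k)
    ord <- idx[order(disc$pos1[idx], disc$pos2[idx])]
    m <- length(ord)
    from <- integer(0); to <- integer(0)
    if (m > 1) {
      for (a in 1:(m - 1)) {
        for (b in (a + 1):m) {
          if (disc$pos1[ord[b]] - disc$pos1[ord[a]] > cluster_window) break
          if (abs(disc$pos2[ord[b]] - disc$pos2[ord[a]]) <= cluster_window) {
            from <- c(from, a); to <- c(to, b)
          }
        }
      }
    }
    cl <- uf_clusters(m, from, to)
    cluster_id[ord] <- n_clusters + cl
    n_clusters <- n_clusters + max(cl)
  }
  out <- do.call(rbind, lapply(split(seq_len(n), cluster_id), function(ii) {
    d <- disc[ii, , drop = FALSE]
    bp1 <- if (d$strand1[1] == "+") max(d$pos1) else min(d$pos1)
    bp2 <- if (d$strand2[1] == "+") max(d$pos2) else min(d$pos2)
    data.frame(chrom1 = d$chrom1[1], pos1 = bp1, strand1 = d$strand1[1],
               chrom2 = d$chrom2[1], pos2 = bp2, strand2 = d$strand2[1],
               support = length(ii))
  }))
  out <- out[out$support >= min_cluster, , drop = FALSE]
  out <- out[order(out$chrom1, out$pos1, out$chrom2, out$pos2), , drop = FALSE]
  junction_table(out$chrom1, out$pos1, out$strand1, out$chrom2, out$pos2,
                 out$strand2, out$support)
}
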