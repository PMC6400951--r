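## Maximum bipartite matching (Kuhn's augmenting-path algorithm) on a logical
## adjacency matrix; columns are tried in ascending `cost` order so that,
## among maximum matchings, pairs at the smallest breakpoint distance are
## preferred deterministically.
max_bipartite_matching <- function(adj, cost = NULL) {
  na <- nrow(adj); nb <- ncol(adj)
  env <- new.env()
  env$match_b <- rep(NA_integer_, nb)
  if (is.null(cost)) cost <- matrix(0, na, nb)
  try_augment <- function(u) {
    ord <- order(cost[u, ], decreasing = FALSE)
    for (v in ord) {
      if (adj[u, v] && !env$visited[v]) {
        env$visited[v] <- TRUE
        if (is.na(env$match_b[v]) || try_augment(env$match_b[v])) {
          env$match_b[v] <- u
          return(TRUE)
        }
      }
    }
    FALSE
  }
  if (na && nb) {
    for (u in seq_len(na)) {
      env$visited <- rep(FALSE, nb)
      try_augment(u)
    }
  }
  list(size = sum(!is.na(env$match_b)), match_b = env$match_b)
}

## Shared junction count between two somatic call sets: size of a maximum
## one-to-one matching under match_junctions.
shared_junction_count <- function(a, b, tolerance = 1e4) {
  if (!nrow(a$junctions) || !nrow(b$junctions)) return(0L)
  adj <- junction_match_matrix(a$junctions, b$junctions, tolerance)
  cost <- abs(outer(a$junctions$pos1, b$junctions$pos1, "-")) +
    abs(outer(a$junctions$pos2, b$junctions$pos2, "-"))
  max_bipartite_matching(adj, cost)$size
}

#' Pairwise shared/unique junction matrix for one patient
#'
#' For every pair of germline-subtracted components, the shared count is the
#' size of a maximum one-to-one matching of their junctions under
#' [match_junctions()]; unique counts are each set's size minus the shared
#' count. Components with no junctions (possible for GCNIS) share 0 with
#' everything.
#'
#' @param components list of [call_set()]s from the same patient, germline
#'   already subtracted.
#' @param tolerance matching tolerance in bp.
#' @return An object of class `lineage_result`: list with `patient_id`,
#'   `counts` (junctions per component) and `pairs` (data.frame `sample_a`,
#'   `sample_b`, `shared`, `unique_a`, `unique_b`).
#' @export
shared_unique_matrix <- function(components, tolerance = 1e4) {
  pid <- unique(vapply(components, `[[`, "", "patient_id"))
  if (length(pid) > 1) stop_input("components span multiple patients")
  ids <- vapply(components, `[[`, "", "sample_id")
  counts <- stats::setNames(
    vapply(components, function(s) nrow(s$junctions), integer(1)), ids)
  if (length(components) < 2) {
    warning("fewer than 2 components; shared/unique matrix is empty")
    pairs <- data.frame(sample_a = character(), sample_b = character(),
                        shared = integer(), unique_a = integer(),
                        unique_b = integer())
  } else {
    cmb <- utils::combn(length(components), 2)
    pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
      i <- cmb[1, k]; j <- cmb[2, k]
      sh <- shared_junction_count(components[[i]], components[[j]], tolerance)
      data.frame(sample_a = ids[i], sample_b = ids[j], shared = sh,
                 unique_a = counts[[i]] - sh, unique_b = counts[[j]] - sh)
    }))
  }
  structure(list(patient_id = pid, counts = counts, pairs = pairs),
            class = "lineage_result")
}

#' @export
print.lineage_result <- function(x, ...) {
  cat(sprintf("lineage_result for patient %s (%d components)\n",
              x$patient_id, length(x$counts)))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Cross-sample junction equivalence classes
#'
#' Pools junctions from all components and groups them by the transitive
#' closure of pairwise matching, yielding the equivalence classes that play
#' the role of characters in lineage reconstruction.
#'
#' @param components list of [call_set()]s.
#' @param tolerance matching tolerance in bp.
#' @return List with `classes` (data.frame `sample_id`, `id`, `class`) and
#'   `presence` (logical matrix, classes x components).
#' @export
junction_equivalence_classes <- function(components, tolerance = 1e4) {
  ids <- vapply(components, `[[`, "", "sample_id")
  pool <- do.call(rbind, lapply(components, function(s) {
    j <- s$junctions
    if (!nrow(j)) return(NULL)
    cbind(j[, c("id", "chrom1", "pos1", "strand1", "chrom2", "pos2",
                "strand2", "support")],
          sample_id = s$sample_id)
  }))
  if (is.null(pool) || !nrow(pool)) {
    return(list(classes = data.frame(sample_id = character(), id = character(),
                                     class = integer()),
                presence = matrix(FALSE, 0, length(ids),
                                  dimnames = list(NULL, ids))))
  }
  mm <- junction_match_matrix(pool, pool, tolerance)
  link <- which(mm & upper.tri(mm), arr.ind = TRUE)
  cl <- uf_clusters(nrow(pool), link[, 1], link[, 2])
  presence <- matrix(FALSE, max(cl), length(ids),
                     dimnames = list(NULL, ids))
  for (k in seq_len(nrow(pool)))
    presence[cl[k], pool$sample_id[k]] <- TRUE
  list(classes = data.frame(sample_id = pool$sample_id, id = pool$id,
                            class = cl),
       presence = presence)
}

#' Build a component dendrogram by greedy shared-junction parsimony
#'
#' Junctions are collapsed into cross-sample equivalence classes
#' ([junction_equivalence_classes()]); components are then merged bottom-up,
#' at each step joining the pair of clusters sharing the most classes
#' (classes present in every leaf of the merged cluster). Clusters sharing
#' zero classes attach at the root as independent lineages. Each node's edge
#' is labelled with the number of classes present in all and only its
#' descendant leaves; for a leaf this is its private-junction count.
#'
#' @param components list of [call_set()]s (>= 2), germline already
#'   subtracted.
#' @param tolerance matching tolerance in bp.
#' @return An object of class `junction_dendrogram`: list with `newick`,
#'   `phylo` (an [ape::read.tree()] tree whose edge lengths are the junction
#'   counts), `node_labels` (named numeric: leaf and clade labels), `clades`
#'   (list of internal-node leaf sets), `n_classes`, and the `presence`
#'   matrix.
#' @export
build_dendrogram <- function(components, tolerance = 1e4) {
  if (length(components) < 2) stop_input("need >= 2 components")
  ids <- vapply(components, `[[`, "", "sample_id")
  eq <- junction_equivalence_classes(components, tolerance)
  presence <- eq$presence
  K <- nrow(presence)

  label_of <- function(leaves) {
    if (!K) return(0L)
    inset <- rowSums(presence[, leaves, drop = FALSE]) == length(leaves)
    outset <- rowSums(presence[, setdiff(ids, leaves), drop = FALSE]) == 0
    sum(inset & (if (length(setdiff(ids, leaves))) outset else TRUE))
  }
  shared_of <- function(leaves) {
    if (!K) return(0L)
    sum(rowSums(presence[, leaves, drop = FALSE]) == length(leaves))
  }

  ## clusters as lists: leaves, newick string
  clusters <- lapply(ids, function(s)
    list(leaves = s, newick = sprintf("%s:%d", s, label_of(s))))
  clades <- list()
  node_labels <- stats::setNames(
    vapply(ids, label_of, integer(1)), ids)

  while (length(clusters) > 1) {
    best <- NULL; best_sh <- 0
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        sh <- shared_of(c(clusters[[i]]$leaves, clusters[[j]]$leaves))
        if (sh > best_sh) { best_sh <- sh; best <- c(i, j) }
      }
    }
    if (is.null(best)) break  # nothing shared: remaining clusters join at root
    i <- best[1]; j <- best[2]
    leaves <- c(clusters[[i]]$leaves, clusters[[j]]$leaves)
    lab <- label_of(leaves)
    merged <- list(
      leaves = leaves,
      newick = sprintf("(%s,%s)%d:%d", clusters[[i]]$newick,
                       clusters[[j]]$newick, lab, lab))
    clades <- c(clades, list(sort(leaves)))
    node_labels[[paste(sort(leaves), collapse = "|")]] <- lab
    clusters <- c(clusters[-c(i, j)], list(merged))
  }
  if (length(clusters) > 1) {
    root_lab <- label_of(ids)
    newick <- sprintf("(%s)%d;",
                      paste(vapply(clusters, `[[`, "", "newick"),
                            collapse = ","), root_lab)
    clades <- c(clades, list(sort(ids)))
    node_labels[[paste(sort(ids), collapse = "|")]] <- root_lab
  } else {
    newick <- paste0(clusters[[1]]$newick, ";")
    ## strip the root's own branch length for a tidy newick
    newick <- sub(":[0-9]+;$", ";", newick)
  }
  phylo <- ape::read.tree(text = newick)
  structure(list(newick = newick, phylo = phylo, node_labels = node_labels,
                 clades = clades, n_classes = K, presence = presence),
            class = "junction_dendrogram")
}

#' @export
print.junction_dendrogram <- function(x, ...) {
  cat("junction_dendrogram:", x$newick, "\n")
  cat(sprintf("  %d junction equivalence classes over %d components\n",
              x$n_classes, ncol(x$presence)))
  invisible(x)
}

#' Compare dendrogram topologies
#'
#' Two dendrograms have the same topology when they have the same leaves and
#' the same set of non-trivial clades (internal-node leaf sets).
#'
#' @param a,b `junction_dendrogram` objects.
#' @return TRUE/FALSE.
#' @export
same_topology <- function(a, b) {
  la <- colnames(a$presence); lb <- colnames(b$presence)
  if (!setequal(la, lb)) return(FALSE)
  ca <- lapply(a$clades, sort); cb <- lapply(b$clades, sort)
  keys_a <- sort(vapply(ca, paste, "", collapse = "|"))
  keys_b <- sort(vapply(cb, paste, "", collapse = "|"))
  identical(keys_a, keys_b)
}

#' Cohort-level junction summary
#'
#' Summarises somatic junction burden across a cohort: per-histology median
#' and range of junction counts, inter- vs intrachromosomal totals, the
#' median intrachromosomal size and the fraction of intrachromosomal
#' junctions below a size cutoff.
#'
#' @param all_samples list of [call_set()]s (germline-subtracted somatic
#'   sets).
#' @param size_cutoff intrachromosomal size cutoff in bp (default 300 kb).
#' @return An object of class `cohort_summary`.
#' @export
cohort_summary <- function(all_samples, size_cutoff = 3e5) {
  if (!length(all_samples)) stop_input("empty cohort")
  hist <- vapply(all_samples, `[[`, "", "histology")
  if (!all(hist %in% HISTOLOGIES))
    stop_input("unknown histology label in cohort")
  counts <- vapply(all_samples, function(s) nrow(s$junctions), integer(1))
  per_hist <- do.call(rbind, lapply(sort(unique(hist)), function(h) {
    x <- counts[hist == h]
    data.frame(histology = h, n_samples = length(x),
               median = stats::median(x), min = min(x), max = max(x))
  }))
  all_j <- do.call(rbind, lapply(all_samples, function(s)
    s$junctions[, c("chrom1", "pos1", "chrom2", "pos2")]))
  if (is.null(all_j) || !nrow(all_j)) {
    inter <- intra <- 0L
    intra_sizes <- numeric()
  } else {
    is_intra <- all_j$chrom1 == all_j$chrom2
    inter <- sum(!is_intra); intra <- sum(is_intra)
    intra_sizes <- abs(all_j$pos2 - all_j$pos1)[is_intra]
  }
  structure(list(
    per_histology = per_hist,
    inter_count = inter, intra_count = intra,
    intra_median_size = if (length(intra_sizes)) stats::median(intra_sizes)
                        else NA_real_,
    frac_intra_below_cutoff = if (length(intra_sizes))
      mean(intra_sizes < size_cutoff) else NA_real_,
    size_cutoff = size_cutoff), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("cohort_summary\n")
  print(x$per_histology, row.names = FALSE)
  cat(sprintf("  %d interchromosomal, %d intrachromosomal junctions\n",
              x$inter_count, x$intra_count))
  if (!is.na(x$intra_median_size))
    cat(sprintf("  intrachromosomal median size %.0f bp; %.1f%% below %.0f bp\n",
                x$intra_median_size, 100 * x$frac_intra_below_cutoff,
                x$size_cutoff))
  invisible(x)
}
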