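# Independent brute-force oracles used to cross-check the package's
# implementations on small instances. These deliberately avoid the package's
# own clustering/matching code paths.

# pairwise-link relation between discordant fragments (same end chromosomes
# and orientations, both positional gaps within the window)
oracle_link_matrix <- function(d, window) {
  key <- paste(d$chrom1, d$strand1, d$chrom2, d$strand2)
  outer(key, key, "==") &
    abs(outer(d$pos1, d$pos1, "-")) <= window &
    abs(outer(d$pos2, d$pos2, "-")) <= window
}

# transitive closure of the link relation by breadth-first search
oracle_transitive_clusters <- function(d, window) {
  n <- nrow(d)
  M <- oracle_link_matrix(d, window)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    frontier <- i
    comp[i] <- k
    while (length(frontier)) {
      nbr <- which(colSums(M[frontier, , drop = FALSE]) > 0 & is.na(comp))
      comp[nbr] <- k
      frontier <- nbr
    }
  }
  comp
}

# junction table implied by an oracle clustering: innermost ends + support
oracle_junctions_from_clusters <- function(d, comp) {
  out <- do.call(rbind, lapply(split(seq_len(nrow(d)), comp), function(ii) {
    x <- d[ii, , drop = FALSE]
    data.frame(chrom1 = x$chrom1[1],
               pos1 = if (x$strand1[1] == "+") max(x$pos1) else min(x$pos1),
               strand1 = x$strand1[1],
               chrom2 = x$chrom2[1],
               pos2 = if (x$strand2[1] == "+") max(x$pos2) else min(x$pos2),
               strand2 = x$strand2[1],
               support = length(ii))
  }))
  out[order(out$chrom1, out$pos1, out$chrom2, out$pos2, out$support), ]
}

# maximum bipartite matching size via igraph (independent of the package's
# Kuhn implementation); edges enumerated with the scalar match predicate
oracle_max_shared <- function(a, b, tolerance) {
  ja <- a$junctions; jb <- b$junctions
  na <- nrow(ja); nb <- nrow(jb)
  if (!na || !nb) return(0L)
  edges <- integer(0)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (match_junctions(ja[i, ], jb[j, ], tolerance))
        edges <- c(edges, i, na + j)
    }
  }
  if (!length(edges)) return(0L)
  g <- igraph::make_empty_graph(n = na + nb, directed = FALSE)
  g <- igraph::add_edges(g, edges)
  igraph::V(g)$type <- c(rep(FALSE, na), rep(TRUE, nb))
  igraph::max_bipartite_match(g)$matching_size
}

# match adjacency re-derived from the definition (row-wise vector
# comparisons, independent of the package's matrix helper), for the igraph
# matching oracle on larger batches
oracle_adjacency <- function(ja, jb, tolerance) {
  t(vapply(seq_len(nrow(ja)), function(i) {
    ja$chrom1[i] == jb$chrom1 & ja$chrom2[i] == jb$chrom2 &
      ja$strand1[i] == jb$strand1 & ja$strand2[i] == jb$strand2 &
      abs(ja$pos1[i] - jb$pos1) <= tolerance &
      abs(ja$pos2[i] - jb$pos2) <= tolerance
  }, logical(nrow(jb))))
}

oracle_max_matching_size <- function(adj) {
  na <- nrow(adj); nb <- ncol(adj)
  idx <- which(adj, arr.ind = TRUE)
  if (!nrow(idx)) return(0L)
  g <- igraph::make_empty_graph(n = na + nb, directed = FALSE)
  g <- igraph::add_edges(g, rbind(idx[, 1], na + idx[, 2]))
  igraph::V(g)$type <- c(rep(FALSE, na), rep(TRUE, nb))
  igraph::max_bipartite_match(g)$matching_size
}

# brute-force germline subtraction: drop every tumour junction matching any
# normal junction, scalar predicate, all pairs
oracle_subtract <- function(tumour, normal, tolerance) {
  jt <- tumour$junctions; jn <- normal$junctions
  if (!nrow(jt) || !nrow(jn)) return(jt$id)
  keep <- vapply(seq_len(nrow(jt)), function(i) {
    !any(vapply(seq_len(nrow(jn)), function(k)
      match_junctions(jt[i, ], jn[k, ], tolerance), logical(1)))
  }, logical(1))
  jt$id[keep]
}

# brute-force point-in-interval gene overlap
oracle_gene_overlap <- function(genome, chrom, pos) {
  g <- genome$genes
  vapply(seq_along(chrom), function(i) {
    hit <- g$chrom == chrom[i] & g$start <= pos[i] & pos[i] < g$end
    if (any(hit)) paste(sort(g$gene[hit]), collapse = ",") else NA_character_
  }, character(1))
}

# random junction call sets with a planted overlap, for matching tests
random_overlap_pair <- function(genome, n_shared, n_only_a, n_only_b,
                                jitter = 5000, patient = "PX") {
  cfg <- sim_config()
  base <- simulate_junction_positions(n_shared + n_only_a + n_only_b,
                                      genome, cfg)
  jit <- function(j, amount) {
    j$pos1 <- pmax(1, j$pos1 + sample(-amount:amount, nrow(j), replace = TRUE))
    j$pos2 <- pmax(1, j$pos2 + sample(-amount:amount, nrow(j), replace = TRUE))
    svlineage:::canonicalize_junctions(j)
  }
  a <- base[seq_len(n_shared + n_only_a), , drop = FALSE]
  b <- rbind(jit(base[seq_len(n_shared), , drop = FALSE], jitter),
             base[n_shared + n_only_a + seq_len(n_only_b), , drop = FALSE])
  a$id <- sprintf("A%03d", seq_len(nrow(a)))
  b$id <- sprintf("B%03d", seq_len(nrow(b)))
  list(a = call_set("SA", patient, "teratoma", a),
       b = call_set("SB", patient, "yolk_sac", b))
}
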