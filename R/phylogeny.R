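#' Clone phylogeny
#'
#' Describes the clonal evolution assumed to have produced a patient's
#' histologic components: histology-labelled clones connected by parent/child
#' edges, each edge carrying counts of the somatic events (junctions, arm
#' copy-number changes, whole-chromosome copy-neutral LOH events, coding
#' mutations) acquired on that edge. The root is the normal/germline clone.
#'
#' @param nodes data.frame with columns `id`, `histology`.
#' @param edges data.frame with columns `parent`, `child`, `junctions`,
#'   `cnvs`, `cnloh`, `mutations` (event counts, all >= 0).
#'
#' @return An object of class `clone_phylogeny`.
#' @export
clone_phylogeny <- function(nodes, edges) {
  stopifnot(all(c("id", "histology") %in% names(nodes)))
  need <- c("parent", "child", "junctions", "cnvs", "cnloh", "mutations")
  miss <- setdiff(need, names(edges))
  for (m in miss) edges[[m]] <- if (m %in% c("parent", "child")) character() else 0
  if (anyDuplicated(nodes$id)) stop_input("node ids must be unique")
  if (!all(nodes$histology %in% HISTOLOGIES))
    stop_input("unknown histology label in phylogeny nodes")
  if (nrow(edges)) {
    if (!all(c(edges$parent, edges$child) %in% nodes$id))
      stop_input("edges reference unknown nodes")
    cnt <- edges[, c("junctions", "cnvs", "cnloh", "mutations")]
    if (any(unlist(cnt) < 0)) stop_input("edge event counts must be >= 0")
    if (anyDuplicated(edges$child))
      stop_input("invalid phylogeny: node with two parents")
  }
  roots <- setdiff(nodes$id, edges$child)
  if (length(roots) != 1L)
    stop_input("invalid phylogeny: exactly one root required, found ",
               length(roots))
  ## reachability + acyclicity by BFS from root
  seen <- roots
  frontier <- roots
  while (length(frontier)) {
    nxt <- edges$child[edges$parent %in% frontier]
    if (any(nxt %in% seen)) stop_input("invalid phylogeny: cycle detected")
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (!setequal(seen, nodes$id))
    stop_input("invalid phylogeny: unreachable nodes: ",
               paste(setdiff(nodes$id, seen), collapse = ", "))
  structure(list(nodes = nodes, edges = edges, root = roots),
            class = "clone_phylogeny")
}

#' @export
print.clone_phylogeny <- function(x, ...) {
  cat(sprintf("clone_phylogeny: %d clones, root = %s\n",
              nrow(x$nodes), x$root))
  if (nrow(x$edges))
    for (i in seq_len(nrow(x$edges)))
      cat(sprintf("  %s -> %s  (junctions %d, cnvs %d, cnloh %d, mutations %d)\n",
                  x$edges$parent[i], x$edges$child[i], x$edges$junctions[i],
                  x$edges$cnvs[i], x$edges$cnloh[i], x$edges$mutations[i]))
  invisible(x)
}

#' Root-to-node edge path
#'
#' @param phylogeny a [clone_phylogeny()].
#' @param node a node id.
#' @return integer vector of edge row indices from the root down to `node`.
#' @export
path_edges <- function(phylogeny, node) {
  e <- phylogeny$edges
  path <- integer()
  cur <- node
  while (cur != phylogeny$root) {
    i <- which(e$child == cur)
    if (!length(i)) stop_input("node not reachable: ", node)
    path <- c(i, path)
    cur <- e$parent[i]
  }
  path
}

#' Canonical germ cell tumour evolution model phylogenies
#'
#' Two competing clonal models for how invasive histologies arise from germ
#' cell neoplasia in situ (GCNIS): in the "direct" model seminoma and
#' embryonal carcinoma each derive directly from GCNIS, with teratoma and
#' yolk sac arising from embryonal carcinoma; in the "linear" model embryonal
#' carcinoma derives from seminoma, which derives from GCNIS. Edge junction
#' counts default to values echoing the per-histology somatic burden seen in
#' mixed germ cell tumours (GCNIS lowest, embryonal carcinoma highest).
#'
#' @param model `"direct"` or `"linear"`.
#' @param junctions_per_edge optional named numeric vector overriding the
#'   default junction count of each edge (names `"parent->child"`).
#' @param mutations_per_edge mean coding mutations per invasive edge.
#' @param cnvs_per_edge mean arm-level copy events per invasive edge.
#' @param cnloh_per_edge mean whole-chromosome cnLOH events per invasive edge.
#'
#' @return A [clone_phylogeny()].
#' @export
phylogeny_model <- function(model = c("direct", "linear"),
                            junctions_per_edge = NULL,
                            mutations_per_edge = 5,
                            cnvs_per_edge = 2,
                            cnloh_per_edge = 1) {
  model <- match.arg(model)
  if (model == "direct") {
    e <- data.frame(
      parent = c("normal", "GCNIS", "GCNIS", "embryonal_carcinoma",
                 "embryonal_carcinoma"),
      child = c("GCNIS", "seminoma", "embryonal_carcinoma", "teratoma",
                "yolk_sac"))
    jn <- c(1, 5, 7, 4, 4)
  } else {
    e <- data.frame(
      parent = c("normal", "GCNIS", "seminoma", "embryonal_carcinoma"),
      child = c("GCNIS", "seminoma", "embryonal_carcinoma", "teratoma"))
    jn <- c(1, 5, 6, 4)
  }
  key <- paste0(e$parent, "->", e$child)
  if (!is.null(junctions_per_edge)) {
    hit <- key %in% names(junctions_per_edge)
    jn[hit] <- junctions_per_edge[key[hit]]
  }
  invasive <- is_invasive_histology(e$child)
  edges <- data.frame(e, junctions = jn,
                      cnvs = ifelse(invasive, cnvs_per_edge, 0),
                      cnloh = ifelse(invasive, cnloh_per_edge, 0),
                      mutations = ifelse(invasive, mutations_per_edge, 1))
  nodes <- data.frame(id = unique(c(e$parent, e$child)))
  nodes$histology <- nodes$id
  clone_phylogeny(nodes, edges)
}

#' Restrict a phylogeny to a set of sampled components
#'
#' Keeps the named nodes plus all their ancestors; edge event counts are
#' unchanged, so unsampled intermediate clones still contribute their events
#' to descendants' root-to-node paths.
#'
#' @param phylogeny a [clone_phylogeny()].
#' @param keep node ids to retain (root is always retained).
#' @return A [clone_phylogeny()].
#' @export
prune_phylogeny <- function(phylogeny, keep) {
  needed <- phylogeny$root
  for (k in keep) {
    p <- path_edges(phylogeny, k)
    needed <- union(needed, c(phylogeny$edges$parent[p],
                              phylogeny$edges$child[p]))
  }
  nodes <- phylogeny$nodes[phylogeny$nodes$id %in% needed, , drop = FALSE]
  edges <- phylogeny$edges[phylogeny$edges$child %in% needed, , drop = FALSE]
  clone_phylogeny(nodes, edges)
}
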