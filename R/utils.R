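#' @keywords internal
"_PACKAGE"

## Controlled histology vocabulary used throughout the package.
HISTOLOGIES <- c("normal", "GCNIS", "seminoma", "embryonal_carcinoma",
                 "teratoma", "yolk_sac")

#' Histology labels recognised by the package
#'
#' @return Character vector of the six controlled histology labels.
#' @export
histology_levels <- function() HISTOLOGIES

is_invasive_histology <- function(h) !(h %in% c("normal", "GCNIS"))

stop_input <- function(...) stop(..., call. = FALSE)

## Minimal union-find with path halving; ids are 1..n.
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

## Returns cluster membership (1..k) for a set of undirected links.
uf_clusters <- function(n, from, to) {
  parent <- uf_new(n)
  for (k in seq_along(from)) {
    ri <- uf_find(parent, from[k])
    rj <- uf_find(parent, to[k])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  match(roots, unique(roots))
}

## Deterministic per-patient/per-stage seed derived from a master seed,
## kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483647)
}
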