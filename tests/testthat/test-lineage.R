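mk_set <- function(sid, ids, pos, patient = "P", hist = "teratoma") {
  n <- length(ids)
  call_set(sid, patient, hist,
           junction_table(rep("chr1", n), pos, rep("+", n),
                          rep("chr2", n), pos + 5e5, rep("-", n),
                          support = rep(10, n), id = ids))
}

test_that("shared/unique counts on a constructed overlap", {
  a <- mk_set("A", c("J1", "J2", "J3"), c(1e6, 2e6, 3e6))
  b <- mk_set("B", c("J2p", "J3p", "J4"), c(2e6 + 500, 3e6 + 900, 8e6))
  lr <- shared_unique_matrix(list(a, b), tolerance = 1e4)
  expect_equal(lr$pairs$shared, 2)
  expect_equal(lr$pairs$unique_a, 1)
  expect_equal(lr$pairs$unique_b, 1)
  # disjoint sets share nothing
  d <- mk_set("D", "J9", 15e6)
  lr2 <- shared_unique_matrix(list(a, d))
  expect_equal(lr2$pairs$shared, 0)
  # single component: empty matrix with a warning
  expect_warning(lr3 <- shared_unique_matrix(list(a)), "fewer than 2")
  expect_equal(nrow(lr3$pairs), 0)
  expect_error(shared_unique_matrix(list(a, mk_set("X", "J1", 1e6,
                                                   patient = "Q"))),
               "multiple patients")
})

test_that("shared counts are symmetric and bounded by the smaller set", {
  set.seed(31)
  g <- toy_genome()
  for (rep in 1:5) {
    pair <- random_overlap_pair(g, sample(3:10, 1), sample(0:10, 1),
                                sample(0:10, 1))
    sh_ab <- shared_unique_matrix(list(pair$a, pair$b))$pairs$shared
    sh_ba <- shared_unique_matrix(list(pair$b, pair$a))$pairs$shared
    expect_equal(sh_ab, sh_ba)
    expect_lte(sh_ab, min(nrow(pair$a$junctions), nrow(pair$b$junctions)))
  }
})

test_that("shared counts equal brute-force maximum bipartite matching", {
  skip_if_not_installed("igraph")
  set.seed(32)
  g <- toy_genome()
  for (rep in 1:20) {
    pair <- random_overlap_pair(g, n_shared = sample(3:25, 1),
                                n_only_a = sample(0:25, 1),
                                n_only_b = sample(0:25, 1),
                                jitter = sample(c(3000, 9000, 15000), 1))
    got <- shared_unique_matrix(list(pair$a, pair$b))$pairs$shared
    expect_equal(got, oracle_max_shared(pair$a, pair$b, 1e4))
  }
})

test_that("dendrogram separates an unrelated GCNIS from a shared EC/teratoma clade", {
  # EC and teratoma share 4 junction classes; GCNIS shares none with either
  ec <- mk_set("EC", paste0("S", 1:6), c(1:4 * 1e6, 30e6, 31e6),
               hist = "embryonal_carcinoma")
  te <- mk_set("TER", paste0("T", 1:5), c(1:4 * 1e6 + 800, 40e6))
  gc <- mk_set("GCNIS", "G1", 50e6, hist = "GCNIS")
  d <- build_dendrogram(list(ec, te, gc), tolerance = 1e4)
  expect_true(list(c("EC", "TER")) %in% d$clades ||
                any(vapply(d$clades, identical, logical(1), c("EC", "TER"))))
  # internal edge of the EC/TER clade carries the 4 shared classes
  expect_equal(unname(d$node_labels[["EC|TER"]]), 4)
  # GCNIS attaches at the root; root shares nothing
  expect_equal(unname(d$node_labels[[paste(sort(c("EC", "GCNIS", "TER")),
                                           collapse = "|")]]), 0)
  # leaf labels are private counts
  expect_equal(unname(d$node_labels[["EC"]]), 2)
  expect_equal(unname(d$node_labels[["TER"]]), 1)
  expect_equal(unname(d$node_labels[["GCNIS"]]), 1)
})

test_that("identical call sets collapse into one clade with zero leaf labels", {
  a <- mk_set("A", paste0("J", 1:4), 1:4 * 1e6)
  b <- mk_set("B", paste0("K", 1:4), 1:4 * 1e6 + 300)
  d <- build_dendrogram(list(a, b))
  expect_equal(unname(d$node_labels[["A"]]), 0)
  expect_equal(unname(d$node_labels[["B"]]), 0)
  expect_equal(unname(d$node_labels[["A|B"]]), 4)
  # edge-label accounting: leaf + internal labels sum to the class count
  expect_equal(sum(unlist(d$node_labels)), d$n_classes)
})

test_that("perfect-phylogeny simulations are reconstructed exactly", {
  cfg <- sim_config(false_junction_rate = 0, breakpoint_jitter_sd = 0)
  g <- toy_genome()
  set.seed(33)
  for (rep in 1:5) {
    phy <- phylogeny_model(sample(c("direct", "linear"), 1))
    sim <- simulate_patient(cfg, g, phy, "P1")
    cs <- sim$call_sets
    filtered <- lapply(seq_along(cs), function(i)
      filter_sample(cs[[i]], cs[-i], filter_config(), g))
    names(filtered) <- names(cs)
    som <- lapply(filtered[setdiff(names(cs), "P1_normal")],
                  subtract_germline, normal = filtered[["P1_normal"]])
    d_obs <- build_dendrogram(som)
    truth_sets <- lapply(setdiff(names(cs), "P1_normal"), function(s) {
      tj <- sim$truth$junctions[[s]]
      call_set(s, "P1", cs[[s]]$histology,
               tj[tj$origin != "germline", , drop = FALSE])
    })
    d_exp <- build_dendrogram(truth_sets)
    expect_true(same_topology(d_obs, d_exp))
    # all classes are explained by tree edges on a perfect phylogeny
    expect_equal(sum(unlist(d_obs$node_labels)), d_obs$n_classes)
  }
})

test_that("cohort summary reports per-histology medians, ranges and size stats", {
  sets <- list(
    mk_set("S1", character(0), numeric(0), hist = "GCNIS"),
    mk_set("S2", "a", 1e6, hist = "GCNIS"),
    mk_set("S3", "b", 2e6, hist = "GCNIS"),
    mk_set("S4", sprintf("c%d", 1:4), 1:4 * 1e6, hist = "GCNIS"),
    mk_set("S5", sprintf("d%d", 1:9), 1:9 * 1e6,
           hist = "embryonal_carcinoma"))
  cs <- cohort_summary(sets, size_cutoff = 3e5)
  gc <- cs$per_histology[cs$per_histology$histology == "GCNIS", ]
  expect_equal(gc$median, 1)
  expect_equal(c(gc$min, gc$max), c(0, 4))
  expect_equal(cs$inter_count, 15)   # all constructed junctions chr1->chr2
  expect_equal(cs$intra_count, 0)
  # single sample: median equals its own count
  one <- cohort_summary(sets[5])
  expect_equal(one$per_histology$median, 9)
  expect_error(cohort_summary(list()), "empty")
})

test_that("intrachromosomal size summary matches hand computation", {
  n <- 4
  j <- junction_table(rep("chr3", n), c(1e6, 2e6, 3e6, 4e6), rep("+", n),
                      rep("chr3", n), c(1e6, 2e6, 3e6, 4e6) +
                        c(1e5, 2e5, 4e5, 6e5), rep("-", n),
                      support = rep(10, n), id = sprintf("z%d", 1:n))
  cs <- cohort_summary(list(call_set("S", "P", "seminoma", j)),
                       size_cutoff = 3e5)
  expect_equal(cs$intra_count, 4)
  expect_equal(cs$intra_median_size, 3e5)
  expect_equal(cs$frac_intra_below_cutoff, 0.5)
})
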