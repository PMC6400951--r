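test_that("genome model enforces its invariants", {
  expect_error(genome_model(data.frame(name = "chr1", length = 1e6),
                            c(chr1 = 2e6)), "centromere")
  expect_error(genome_model(data.frame(name = c("chr1", "chr1"),
                                       length = c(1e6, 1e6)),
                            c(chr1 = 5e5)), "unique")
  g <- toy_genome()
  expect_equal(nrow(g$chromosomes), 24)
  arms <- chrom_arms(g)
  expect_true(all(c("12p", "12q", "1p", "Yq") %in% arms$arm))
  expect_true(all(arms$start < arms$end))
  # arm lookup respects the centromere
  expect_equal(unname(svlineage:::arm_of(g, "chr12", 1e6)), "12p")
  expect_equal(unname(svlineage:::arm_of(g, "chr12", 5e6)), "12q")
})

test_that("phylogeny validation rejects cycles, multiple roots, orphans", {
  nodes <- data.frame(id = c("normal", "GCNIS", "seminoma"),
                      histology = c("normal", "GCNIS", "seminoma"))
  expect_error(clone_phylogeny(nodes, data.frame(
    parent = c("normal", "GCNIS", "seminoma"),
    child = c("GCNIS", "seminoma", "GCNIS"))), "two parents")
  expect_error(clone_phylogeny(nodes, data.frame(
    parent = "normal", child = "GCNIS")), "unreachable|root")
  phy <- phylogeny_model("direct")
  expect_equal(phy$root, "normal")
  expect_equal(sort(path_edges(phy, "teratoma")), c(1, 3, 4))
})

test_that("truth junction counts are path sums over the phylogeny", {
  cfg <- sim_config(seed = 7, germline_junctions_per_patient = 5,
                    false_junction_rate = 0)
  sim <- simulate_patient(cfg, toy_genome(), linear_phylogeny(2, 8), "P1")
  counts <- vapply(sim$call_sets, function(s) nrow(s$junctions), integer(1))
  expect_equal(unname(counts[c("P1_normal", "P1_GCNIS",
                               "P1_embryonal_carcinoma")]),
               c(5, 7, 15))
  # with no noise, every emitted junction is in the ground truth
  for (s in names(sim$call_sets)) {
    expect_setequal(sim$call_sets[[s]]$junctions$id,
                    sim$truth$junctions[[s]]$id)
  }
})

test_that("somatic truth sets accumulate monotonically along the phylogeny", {
  cfg <- sim_config(seed = 11)
  phy <- phylogeny_model("direct")
  sim <- simulate_patient(cfg, toy_genome(), phy, "P1")
  anc <- function(n) sim$truth$junctions[[paste0("P1_", n)]]$id
  expect_true(all(anc("GCNIS") %in% anc("embryonal_carcinoma")))
  expect_true(all(anc("embryonal_carcinoma") %in% anc("teratoma")))
  expect_true(all(anc("embryonal_carcinoma") %in% anc("yolk_sac")))
  # germline junctions appear in every component including the normal
  gl <- sim$truth$germline$id
  for (s in names(sim$call_sets))
    expect_true(all(gl %in% sim$call_sets[[s]]$junctions$id))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 1)
  g <- toy_genome()
  phy <- phylogeny_model("linear")
  a <- simulate_patient(cfg, g, phy, "P1")
  b <- simulate_patient(cfg, g, phy, "P1")
  expect_identical(a, b)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(i12p_gain_level = 2), "i12p")
  expect_error(sim_config(fragment_size_mean = -1), "fragment_size_mean")
  expect_error(sim_config(false_junction_rate = -1), ">= 0")
})

test_that("emitted junction counts are calibrated to path sum + germline + false rate", {
  cfg <- sim_config(germline_junctions_per_patient = 4,
                    false_junction_rate = 2)
  phy <- linear_phylogeny(2, 8)
  set.seed(99)
  n_rep <- 200
  counts <- vapply(seq_len(n_rep), function(i) {
    sim <- simulate_patient(cfg, toy_genome(), phy, "P",
                            components = "embryonal_carcinoma",
                            include_normal = FALSE)
    nrow(sim$call_sets[["P_embryonal_carcinoma"]]$junctions)
  }, integer(1))
  expected <- 4 + 2 + 8 + 2   # germline + path sum + false rate
  se <- stats::sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("invasive components carry the configured 12p gain, GCNIS/normal stay flat", {
  cfg <- sim_config(seed = 3, i12p_gain_level = 5)
  sim <- simulate_patient(cfg, toy_genome(), phylogeny_model("direct"), "P1")
  st <- sim$truth$arm_states
  expect_equal(unname(st[["P1_embryonal_carcinoma"]]["12p"]), 5)
  expect_equal(unname(st[["P1_teratoma"]]["12p"]), 5)
  expect_equal(unname(st[["P1_GCNIS"]]["12p"]), 2)
  expect_equal(unname(st[["P1_normal"]]["12p"]), 2)
})

test_that("zero-jitter fragments sit exactly on the breakpoints", {
  g <- toy_genome()
  cfg <- sim_config(n_background_fragments = 0)
  j <- junction_table("chr1", 1000000, "+", "chr4", 2000000, "-",
                      support = 9, id = "J1")
  s <- call_set("S1", "P1", "teratoma", j)
  fr <- simulate_fragments(s, cfg, g, jitter = 0)
  expect_equal(nrow(fr), 9)
  expect_true(all(fr$chrom1 == "chr1" & fr$pos1 == 1000000))
  expect_true(all(fr$chrom2 == "chr4" & fr$pos2 == 2000000))
})

test_that("with no junctions only concordant fragments near the library size are emitted", {
  g <- toy_genome()
  cfg <- sim_config(n_background_fragments = 300)
  s <- call_set("S1", "P1", "teratoma", junction_table())
  set.seed(5)
  fr <- simulate_fragments(s, cfg, g)
  expect_equal(nrow(fr), 300)
  expect_true(all(fr$chrom1 == fr$chrom2))
  span <- abs(fr$pos2 - fr$pos1)
  expect_true(all(abs(span - cfg$fragment_size_mean) <
                    6 * cfg$fragment_size_sd))
  expect_true(all(classify_fragments(fr) == "concordant"))
})

test_that("fragments reject junctions outside the genome", {
  g <- toy_genome()
  cfg <- sim_config()
  j <- junction_table("chr1", 9e9, "+", "chr4", 2000000, "-",
                      support = 9, id = "J1")
  s <- call_set("S1", "P1", "teratoma", j)
  expect_error(simulate_fragments(s, cfg, g), "outside genome")
})
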