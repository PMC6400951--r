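frag <- function(chrom1, pos1, strand1, chrom2, pos2, strand2) {
  data.frame(chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
             chrom2 = chrom2, pos2 = pos2, strand2 = strand2)
}

test_that("fragment classification follows chromosome, orientation and span", {
  # interchromosomal ends
  expect_equal(classify_fragment(frag("chr1", 1e6, "+", "chr5", 1e6, "-")),
               "discordant")
  # proper pair at the library size
  expect_equal(classify_fragment(frag("chr1", 1e6, "+", "chr1", 1e6 + 3700,
                                      "-"), fragment_size_mean = 3700),
               "concordant")
  # span beyond the 30 kb event floor
  expect_equal(classify_fragment(frag("chr1", 1e6, "+", "chr1", 1e6 + 80000,
                                      "-"), min_event_size = 30000),
               "discordant")
  # span just inside the floor remains concordant
  expect_equal(classify_fragment(frag("chr1", 1e6, "+", "chr1", 1e6 + 29000,
                                      "-")), "concordant")
  # inverted orientation is discordant regardless of span
  expect_equal(classify_fragment(frag("chr1", 1e6, "+", "chr1", 1e6 + 3700,
                                      "+")), "discordant")
  expect_error(classify_fragment(frag("chr1", 1, "+", "chr1", 2, "-"),
                                 fragment_size_mean = -5), "positive")
})

test_that("identical fragment ends collapse into one junction with full support", {
  fr <- frag(rep("chr1", 9), rep(1000000, 9), rep("+", 9),
             rep("chr4", 9), rep(2000000, 9), rep("-", 9))
  j <- detect_junctions(fr)
  expect_equal(nrow(j), 1)
  expect_equal(j$support, 9)
  expect_equal(j$pos1, 1000000)
  expect_equal(j$pos2, 2000000)
})

test_that("loci far beyond the window yield separate junctions", {
  fr <- rbind(frag(rep("chr1", 3), c(1e6, 1e6 + 100, 1e6 + 200), "+",
                   rep("chr4", 3), c(2e6, 2e6 + 50, 2e6 + 150), "-"),
              frag(rep("chr1", 4), 11e6 + c(0, 10, 20, 30), "+",
                   rep("chr4", 4), 12e6 + c(0, 10, 20, 30), "-"))
  j <- detect_junctions(fr, cluster_window = 7400)
  expect_equal(nrow(j), 2)
  expect_equal(sort(j$support), c(3, 4))
})

test_that("breakpoint estimate is the orientation-aware innermost end", {
  # '+' side: maximal position; '-' side: minimal position
  fr <- frag(rep("chr2", 5), c(100, 300, 250, 120, 180), "+",
             rep("chr3", 5), c(5100, 5300, 5250, 5120, 5180), "-")
  j <- detect_junctions(fr)
  expect_equal(j$pos1, 300)
  expect_equal(j$pos2, 5100)
})

test_that("detection equals brute-force transitive closure on random instances", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(20:200, 1)
    # few chromosome-pair keys so clusters and chains actually interact
    k <- sample(1:3, n, replace = TRUE)
    fr <- frag(c("chr1", "chr2", "chr1")[k],
               round(stats::runif(n, 0, 5e4)),
               c("+", "+", "-")[k],
               c("chr2", "chr2", "chr5")[k],
               round(stats::runif(n, 1e6, 1e6 + 5e4)),
               c("-", "+", "-")[k])
    win <- sample(c(2000, 7400), 1)
    got <- detect_junctions(fr, cluster_window = win)
    comp <- oracle_transitive_clusters(fr, win)
    want <- oracle_junctions_from_clusters(fr, comp)
    got_df <- as.data.frame(got[, names(want)])
    got_df <- got_df[order(got_df$chrom1, got_df$pos1, got_df$chrom2,
                           got_df$pos2, got_df$support), ]
    rownames(got_df) <- rownames(want) <- NULL
    expect_equal(got_df, want)
    # sum of supports equals the number of clustered discordant fragments
    expect_equal(sum(got$support), n)
  }
})

test_that("fragment input order does not change the detected junction set", {
  set.seed(7)
  g <- toy_genome()
  cfg <- sim_config(seed = NULL, n_background_fragments = 200)
  phy <- phylogeny_model("direct")
  sim <- simulate_patient(cfg, g, phy, "P1")
  fr <- simulate_fragments(sim$call_sets[[2]], cfg, g)
  fr$sample_id <- NULL
  a <- detect_junctions(fr)
  b <- detect_junctions(fr[sample(nrow(fr)), ])
  cols <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2",
            "support")
  expect_equal(as.data.frame(a[, cols]), as.data.frame(b[, cols]))
})

test_that("detection rejects mixed-sample input", {
  fr <- frag("chr1", 1, "+", "chr2", 2, "-")
  fr <- rbind(fr, fr)
  fr$sample_id <- c("A", "B")
  expect_error(detect_junctions(fr), "single sample")
})

test_that("detection recovers simulated junctions at default jitter", {
  g <- toy_genome()
  cfg <- sim_config(n_background_fragments = 500)
  set.seed(101)
  recovered <- 0; total <- 0
  for (rep in 1:20) {
    phy <- phylogeny_model(sample(c("direct", "linear"), 1))
    sim <- simulate_patient(cfg, g, phy, "P1",
                            components = "teratoma", include_normal = FALSE)
    s <- sim$call_sets[["P1_teratoma"]]
    truth <- s$junctions[s$junctions$support >= 7, ]
    fr <- simulate_fragments(s, cfg, g)
    det <- detect_junctions(fr, cluster_window = 2 * cfg$fragment_size_mean)
    mm <- svlineage:::junction_match_matrix(truth, det,
                                            2 * cfg$fragment_size_mean)
    recovered <- recovered + sum(rowSums(mm) > 0)
    total <- total + nrow(truth)
  }
  expect_gte(recovered / total, 0.95)
})
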