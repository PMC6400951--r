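flat_karyotype <- function(genome, states = NULL) {
  set.seed(1000)
  call_arm_states(simulate_depth_profile(genome, states), genome)
}

test_that("balanced allele fractions at 2N are called normal", {
  g <- toy_genome()
  set.seed(41)
  sites <- simulate_het_sites(g, snp_density = 5)
  prof <- simulate_allele_profile(g, sites, snp_depth = 100, normal = FALSE)
  calls <- call_cnloh(prof, flat_karyotype(g))
  called <- calls[calls$call != "no_call", ]
  expect_true(all(called$call == "normal"))
  # chromosomes below the informative-site floor are no-called
  small <- calls$chrom[calls$n_sites < 20]
  expect_true(all(calls$call[calls$chrom %in% small] == "no_call"))
})

test_that("allele fractions near 0/1 at 2N are called cnLOH, not at other states", {
  g <- toy_genome()
  set.seed(42)
  sites <- simulate_het_sites(g, snp_density = 5)
  prof <- simulate_allele_profile(g, sites, cnloh_chroms = c("chr10", "chr22"),
                                  snp_depth = 100)
  calls <- call_cnloh(prof, flat_karyotype(g))
  expect_equal(sort(calls$chrom[calls$call == "cnLOH"]),
               c("chr10", "chr22"))
  # same allelic pattern on a lost chromosome is LOH_with_loss: the
  # copy-neutral label is reserved for 2N chromosomes by definition
  prof2 <- simulate_allele_profile(g, sites, arm_states = c("9p" = 1, "9q" = 1),
                                   cnloh_chroms = character(), snp_depth = 100)
  k2 <- flat_karyotype(g, c("9p" = 1, "9q" = 1))
  calls2 <- call_cnloh(prof2, k2)
  expect_equal(calls2$call[calls2$chrom == "chr9"], "LOH_with_loss")
  expect_false(any(calls2$call == "cnLOH" &
                     (calls2$state_p != 2 | calls2$state_q != 2)))
})

test_that("deviant-site counting is monotone in the deviation threshold", {
  g <- toy_genome()
  set.seed(43)
  sites <- simulate_het_sites(g, 5)
  prof <- simulate_allele_profile(g, sites, cnloh_chroms = "chr4",
                                  snp_depth = 40)
  k <- flat_karyotype(g)
  lo <- call_cnloh(prof, k, deviation_threshold = 0.1)
  hi <- call_cnloh(prof, k, deviation_threshold = 0.3)
  expect_true(all(hi$fraction_deviant <= lo$fraction_deviant))
})

test_that("tumour-only allele profiles are refused for cnLOH", {
  g <- toy_genome()
  set.seed(44)
  prof <- simulate_allele_profile(g, simulate_het_sites(g, 5))
  attr(prof, "het_sites_from_normal") <- FALSE
  expect_error(call_cnloh(prof, flat_karyotype(g)), "matched normal")
})

test_that("the mutation-filter fixture yields the hand-derived retained set", {
  fx <- make_mutation_fixture()
  out <- filter_mutations(fx$table, min_depth = 20)
  expect_equal(out$id, fx$expected_kept)
  # idempotent and order-preserving
  expect_identical(filter_mutations(out), out)
  # empty input passes through
  expect_equal(nrow(filter_mutations(fx$table[0, ])), 0)
  bad <- fx$table
  bad$consequence[1] <- "promoter"
  expect_error(filter_mutations(bad), "unknown consequence")
})

test_that("shared mutations are the exact-key intersection, symmetric and bounded", {
  fx <- make_mutation_fixture()
  a <- fx$table[1:8, ]
  b <- fx$table[5:12, ]
  sh <- shared_mutations(a, b)
  expect_equal(sh$id, sprintf("M%02d", 5:8))
  expect_equal(nrow(shared_mutations(b, a)), nrow(sh))
  expect_lte(nrow(sh), min(nrow(a), nrow(b)))
  expect_equal(nrow(shared_mutations(a, a)), nrow(a))          # identity
  expect_equal(nrow(shared_mutations(a[1:2, ], b[1:2, ])), 0)  # disjoint
})

test_that("shared mutation counts equal ground-truth path intersections", {
  cfg <- sim_config(seed = 45)
  g <- toy_genome()
  sim <- simulate_patient(cfg, g, phylogeny_model("direct"), "P1")
  ids <- setdiff(names(sim$mutation_tables), "P1_normal")
  filt <- lapply(sim$mutation_tables[ids], filter_mutations)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      got <- nrow(shared_mutations(filt[[i]], filt[[j]]))
      want <- length(intersect(sim$truth$mutations[[ids[i]]]$id,
                               sim$truth$mutations[[ids[j]]]$id))
      expect_equal(got, want)
    }
  }
})

test_that("cancer-gene annotation equals a brute-force interval scan", {
  g <- toy_genome()
  set.seed(46)
  j <- simulate_junction_positions(60, g, sim_config())
  ann <- annotate_cancer_genes(j, g)
  expect_equal(ann$gene1, oracle_gene_overlap(g, j$chrom1, j$pos1))
  expect_equal(ann$gene2, oracle_gene_overlap(g, j$chrom2, j$pos2))
  # breakpoint inside a listed cancer gene is flagged
  cg <- g$genes[g$genes$gene == g$cancer_genes[1], ]
  jc <- junction_table(cg$chrom, cg$start + 10, "+", "chr2", 5e6, "-",
                       support = 10, id = "hit")
  expect_true(annotate_cancer_genes(jc, g)$cancer_gene)
  # both breakpoints intergenic: no flag
  ji <- junction_table("chr1", 50, "+", "chr2", 50, "-", support = 10,
                       id = "miss")
  ai <- annotate_cancer_genes(ji, g)
  expect_true(is.na(ai$gene1) && is.na(ai$gene2) && !ai$cancer_gene)
})
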