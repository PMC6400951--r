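# Hand-enumerated fixtures spanning every filter-rule boundary. Gene regions
# of toy_genome() tile [100000, 130000), [250000, 280000), ... (30 kb genic
# every 150 kb), so genic/non-genic positions below are known by construction.

# 20-junction call set exercising support 6/7, rescue 2/3 with related-sample
# support 6/7/9, intrachromosomal sizes 45 kb / 50 kb / 75 kb genic /
# 75 kb non-genic / 100 kb boundary / >100 kb, and interchromosomal exemption.
make_filter_fixture <- function() {
  s <- junction_table(
    chrom1 = c("chr1", "chr1", "chr1", "chr1", "chr1",
               "chr2", "chr2", "chr3", "chr3", "chr4",
               "chr4", "chr5", "chr5", "chr6", "chr6",
               "chr7", "chr7", "chr9", "chr8", "chrX"),
    pos1 = c(500000, 1000000, 1500000, 2000000, 2500000,
             500000, 700000, 110000, 140000, 110000,
             435000, 140000, 440000, 110000, 300000,
             1000000, 55000, 1000000, 1000000, 1000000),
    strand1 = c("+", "+", "+", "+", "+",
                "+", "+", "+", "+", "+",
                "+", "+", "+", "+", "+",
                "+", "+", "-", "+", "+"),
    chrom2 = c("chr2", "chr3", "chr4", "chr5", "chr6",
               "chr2", "chr2", "chr3", "chr3", "chr4",
               "chr4", "chr5", "chr5", "chr6", "chr6",
               "chr8", "chr7", "chr10", "chr8", "chrY"),
    pos2 = c(5000000, 5000000, 5000000, 5000000, 5000000,
             545000, 750000, 185000, 215000, 210000,
             535000, 240001, 590000, 185000, 345000,
             1000000, 110000, 1000000, 3000000, 1000000),
    strand2 = c("-", "-", "-", "-", "-",
                "-", "-", "-", "-", "-",
                "-", "-", "-", "-", "-",
                "+", "-", "-", "-", "-"),
    support = c(7, 6, 3, 2, 6,
                20, 20, 10, 10, 10,
                10, 10, 8, 6, 3,
                100, 10, 3, 7, 1),
    id = sprintf("F%02d", 1:20))
  r <- junction_table(
    chrom1 = c("chr1", "chr1", "chr1", "chr6", "chr9"),
    pos1 = c(1500500, 2000500, 2500500, 300500, 1009999),
    strand1 = c("+", "+", "+", "+", "-"),
    chrom2 = c("chr4", "chr5", "chr6", "chr6", "chr10"),
    pos2 = c(5000500, 5000500, 5000500, 345500, 990001),
    strand2 = c("-", "-", "-", "-", "-"),
    support = c(9, 9, 6, 9, 7),
    id = sprintf("R%02d", 1:5))
  list(
    sample = call_set("SA", "PT", "embryonal_carcinoma", s),
    related = call_set("SR", "PT", "teratoma", r),
    expected_kept = c("F01", "F03", "F08", "F10", "F12", "F13", "F16",
                      "F17", "F18", "F19"))
}

# 12-record mutation table spanning the depth-20 boundary and every
# consequence class
make_mutation_fixture <- function() {
  m <- data.frame(
    id = sprintf("M%02d", 1:12),
    chrom = rep("chr1", 12),
    pos = seq(1e5, by = 1e4, length.out = 12),
    ref = rep("A", 12), alt = rep("G", 12),
    gene = sprintf("G1_%03d", 1:12),
    consequence = c("missense", "missense", "missense", "nonsense",
                    "frameshift", "splice", "synonymous", "intronic",
                    "UTR", "nonsense", "frameshift", "splice"),
    depth_normal = c(25, 19, 20, 100, 21, 50, 100, 50, 30, 19, 20, 20),
    depth_tumour = c(30, 30, 20, 100, 22, 19, 100, 50, 30, 19, 19, 20),
    stringsAsFactors = FALSE)
  list(table = m, expected_kept = c("M01", "M03", "M04", "M05", "M12"))
}

# small linear phylogeny normal -> GCNIS -> embryonal carcinoma with explicit
# edge junction counts, used for path-sum examples
linear_phylogeny <- function(j_gcnis = 2, j_ec = 8, mutations = c(1, 5)) {
  clone_phylogeny(
    nodes = data.frame(id = c("normal", "GCNIS", "embryonal_carcinoma"),
                       histology = c("normal", "GCNIS",
                                     "embryonal_carcinoma")),
    edges = data.frame(parent = c("normal", "GCNIS"),
                       child = c("GCNIS", "embryonal_carcinoma"),
                       junctions = c(j_gcnis, j_ec),
                       cnvs = c(0, 2), cnloh = c(0, 1),
                       mutations = mutations))
}
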