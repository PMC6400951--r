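#' Genome model
#'
#' A lightweight container describing the coordinate system the pipeline works
#' in: chromosome names and lengths, centromere positions splitting each
#' chromosome into a p and a q arm, gene regions used for the genic-region
#' junction filter and breakpoint annotation, and a set of cancer gene names
#' standing in for a curated cancer-gene census list.
#'
#' All coordinates are 0-based half-open.
#'
#' @param chromosomes data.frame with columns `name`, `length` (bp).
#' @param centromeres named numeric vector, one entry per chromosome, strictly
#'   inside `(0, length)`.
#' @param genes data.frame with columns `chrom`, `start`, `end`, `gene`.
#' @param cancer_genes character vector of gene names flagged as cancer genes.
#'
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, centromeres, genes = NULL,
                         cancer_genes = character()) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  if (nrow(chromosomes) == 0L) stop_input("genome must contain >= 1 chromosome")
  if (anyDuplicated(chromosomes$name))
    stop_input("chromosome names must be unique")
  if (any(chromosomes$length <= 0)) stop_input("chromosome lengths must be > 0")
  if (!all(chromosomes$name %in% names(centromeres)))
    stop_input("every chromosome needs a centromere position")
  cen <- centromeres[chromosomes$name]
  if (any(cen <= 0 | cen >= chromosomes$length))
    stop_input("centromeres must lie strictly inside (0, length)")
  if (is.null(genes)) {
    genes <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), gene = character())
  }
  stopifnot(all(c("chrom", "start", "end", "gene") %in% names(genes)))
  if (nrow(genes)) {
    if (!all(genes$chrom %in% chromosomes$name))
      stop_input("gene regions reference unknown chromosomes")
    len <- chromosomes$length[match(genes$chrom, chromosomes$name)]
    if (any(genes$start < 0 | genes$end > len | genes$start >= genes$end))
      stop_input("gene regions must lie within chromosome bounds")
  }
  structure(list(chromosomes = chromosomes, centromeres = cen,
                 genes = genes, cancer_genes = as.character(cancer_genes)),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosomes, %.1f Mb total, %d genes (%d cancer genes)\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
              nrow(x$genes), length(x$cancer_genes)))
  invisible(x)
}

#' Miniature human-like genome
#'
#' Builds a 24-chromosome genome whose chromosome and arm proportions mirror
#' GRCh38 scaled down 10x (~309 Mb total), so that arm-level logic — in
#' particular anything keyed on "12p" — is exercised with its real-world
#' names. Gene regions are laid down deterministically as `gene_length` bp
#' intervals every `gene_spacing` bp starting at 100 kb on each chromosome
#' (20% genic by default); every `cancer_gene_every`-th gene is flagged as a
#' cancer gene.
#'
#' @param scale multiplier on all lengths (1 = the 10x-reduced genome).
#' @param gene_length,gene_spacing gene tile length and period in bp.
#' @param cancer_gene_every flag every n-th gene as a cancer gene.
#'
#' @return A [genome_model()].
#' @export
toy_genome <- function(scale = 1, gene_length = 3e4, gene_spacing = 1.5e5,
                       cancer_gene_every = 25) {
  nm <- c(paste0("chr", 1:22), "chrX", "chrY")
  len <- c(24.9, 24.2, 19.8, 19.0, 18.2, 17.1, 15.9, 14.5, 13.8, 13.4,
           13.5, 13.3, 11.4, 10.7, 10.2, 9.0, 8.3, 8.0, 5.9, 6.4,
           4.7, 5.1, 15.6, 5.7) * 1e6 * scale
  cen <- c(12.3, 9.3, 9.1, 5.0, 4.8, 6.0, 6.0, 4.5, 4.3, 4.0,
           5.3, 3.6, 1.8, 1.7, 1.9, 3.7, 2.5, 1.8, 2.6, 2.8,
           1.2, 1.5, 6.1, 1.0) * 1e6 * scale
  names(cen) <- nm
  genes <- do.call(rbind, lapply(seq_along(nm), function(i) {
    starts <- seq(1e5 * scale, len[i] - gene_length, by = gene_spacing)
    data.frame(chrom = nm[i], start = starts, end = starts + gene_length,
               gene = sprintf("G%s_%03d", sub("^chr", "", nm[i]),
                              seq_along(starts)))
  }))
  cancer <- genes$gene[seq(cancer_gene_every, nrow(genes),
                           by = cancer_gene_every)]
  genome_model(data.frame(name = nm, length = len), cen, genes, cancer)
}

#' Chromosome arms of a genome model
#'
#' @param genome a [genome_model()].
#' @return data.frame with columns `arm` ("12p", "12q", ...), `chrom`,
#'   `start`, `end` (0-based half-open).
#' @export
chrom_arms <- function(genome) {
  ch <- genome$chromosomes
  base <- sub("^chr", "", ch$name)
  cen <- genome$centromeres[ch$name]
  data.frame(
    arm = c(paste0(base, "p"), paste0(base, "q")),
    chrom = c(ch$name, ch$name),
    start = c(rep(0, nrow(ch)), unname(cen)),
    end = c(unname(cen), ch$length),
    row.names = NULL
  )
}

arm_of <- function(genome, chrom, pos) {
  cen <- genome$centromeres[chrom]
  paste0(sub("^chr", "", chrom), ifelse(pos < cen, "p", "q"))
}

## Gene names overlapping point breakpoints; returns a character vector
## (comma-joined names, NA_character_ when intergenic).
gene_hits <- function(genome, chrom, pos) {
  out <- rep(NA_character_, length(chrom))
  if (!nrow(genome$genes) || !length(chrom)) return(out)
  g <- genome$genes
  q <- IRanges::IRanges(start = pos + 1, width = 1)  # 1-based for IRanges
  s <- IRanges::IRanges(start = g$start + 1, end = g$end)
  for (cc in unique(chrom)) {
    qi <- which(chrom == cc)
    si <- which(g$chrom == cc)
    if (!length(si)) next
    ov <- IRanges::findOverlaps(q[qi], s[si])
    if (!length(ov)) next
    hit <- tapply(g$gene[si][S4Vectors::subjectHits(ov)],
                  S4Vectors::queryHits(ov),
                  function(x) paste(sort(x), collapse = ","))
    out[qi[as.integer(names(hit))]] <- unname(hit)
  }
  out
}
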