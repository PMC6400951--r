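#' Call whole-chromosome loss of heterozygosity from SNP allele fractions
#'
#' At sites ascertained as heterozygous in the matched normal, the expected
#' reference-allele fraction is 0.5; LOH and allelic imbalance shift it away.
#' A site is deviant when `|ref_fraction - 0.5| > deviation_threshold`; a
#' chromosome is called LOH when at least `site_fraction` of its informative
#' sites are deviant. The call is labelled copy-neutral (`cnLOH`) only when
#' both arms of the chromosome sit at copy state 2 in the accompanying
#' karyotype — LOH on an aberrant chromosome is labelled `LOH_with_loss` or
#' `LOH_with_gain` instead. Chromosomes with fewer than `min_sites`
#' informative sites, or without karyotype states, are no-called.
#'
#' @param profile an allele profile data.frame (`chrom`, `pos`, `ref_count`,
#'   `alt_count`) whose sites are heterozygous in the matched normal.
#' @param karyotype an `arm_karyotype` from [call_arm_states()].
#' @param deviation_threshold allele-fraction deviation defining a deviant
#'   site (default 0.15; at 30x depth or more a balanced site exceeds this
#'   with negligible binomial probability).
#' @param site_fraction fraction of deviant sites required for a call
#'   (default 0.8).
#' @param min_sites minimal informative sites per chromosome (default 20).
#' @return data.frame, one row per chromosome: `chrom`, `n_sites`,
#'   `fraction_deviant`, `mean_ref_fraction`, `state_p`, `state_q`, `call`
#'   (`normal`, `cnLOH`, `LOH_with_loss`, `LOH_with_gain`, `no_call`).
#' @export
call_cnloh <- function(profile, karyotype, deviation_threshold = 0.15,
                       site_fraction = 0.8, min_sites = 20) {
  if (isFALSE(attr(profile, "het_sites_from_normal")))
    stop_input("cnLOH calling requires sites ascertained as heterozygous ",
               "in the matched normal")
  depth <- profile$ref_count + profile$alt_count
  keep <- depth > 0
  profile <- profile[keep, , drop = FALSE]
  depth <- depth[keep]
  frac <- profile$ref_count / depth
  deviant <- abs(frac - 0.5) > deviation_threshold
  chroms <- unique(profile$chrom)
  out <- do.call(rbind, lapply(chroms, function(cc) {
    i <- profile$chrom == cc
    n <- sum(i)
    base <- sub("^chr", "", cc)
    sp <- karyotype$states[paste0(base, "p")]
    sq <- karyotype$states[paste0(base, "q")]
    fd <- mean(deviant[i])
    call <- if (n < min_sites || is.na(sp) || is.na(sq)) {
      "no_call"
    } else if (fd < site_fraction) {
      "normal"
    } else if (sp == 2 && sq == 2) {
      "cnLOH"
    } else if (sp < 2 || sq < 2) {
      "LOH_with_loss"
    } else {
      "LOH_with_gain"
    }
    data.frame(chrom = cc, n_sites = n, fraction_deviant = fd,
               mean_ref_fraction = mean(frac[i]),
               state_p = unname(sp), state_q = unname(sq), call = call)
  }))
  rownames(out) <- NULL
  out
}

MUTATION_CONSEQUENCES <- c("missense", "nonsense", "frameshift", "splice",
                           "synonymous", "intronic", "UTR")
PROTEIN_IMPACTING <- c("missense", "nonsense", "frameshift", "splice")

#' Filter somatic mutations by coverage and consequence
#'
#' Retains mutations covered by at least `min_depth` reads in both the normal
#' and the tumour sample whose consequence impacts the final protein product
#' (missense, nonsense, frameshift, splice); intronic, untranslated-region
#' and synonymous calls are removed as likely false-positive sources.
#'
#' @param muts data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `consequence`, `depth_normal`, `depth_tumour` (order preserved).
#' @param min_depth minimal coverage in both samples (default 20, inclusive).
#' @return The retained rows, in input order.
#' @export
filter_mutations <- function(muts, min_depth = 20) {
  if (!nrow(muts)) return(muts)
  if (!all(muts$consequence %in% MUTATION_CONSEQUENCES))
    stop_input("unknown consequence class: ",
               paste(setdiff(muts$consequence, MUTATION_CONSEQUENCES),
                     collapse = ", "))
  keep <- muts$depth_normal >= min_depth & muts$depth_tumour >= min_depth &
    muts$consequence %in% PROTEIN_IMPACTING
  out <- muts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mutations shared between two components
#'
#' Exact-key intersection on (chromosome, position, ref, alt); both inputs
#' should already be filtered with [filter_mutations()].
#'
#' @param a,b mutation data.frames.
#' @return The rows of `a` whose key also occurs in `b`.
#' @export
shared_mutations <- function(a, b) {
  key <- function(m) paste(m$chrom, m$pos, m$ref, m$alt, sep = ":")
  out <- a[key(a) %in% key(b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate junction breakpoints with gene and cancer-gene hits
#'
#' Flags each junction with the gene regions overlapped by either breakpoint
#' and whether any of them is in the genome model's cancer-gene list (a
#' user-supplied stand-in for a cancer gene census).
#'
#' @param junctions a [junction_table()].
#' @param genome a [genome_model()] with gene regions loaded.
#' @return The junction table with added columns `gene1`, `gene2`
#'   (comma-joined overlapping gene names or `NA`) and `cancer_gene`
#'   (logical).
#' @export
annotate_cancer_genes <- function(junctions, genome) {
  if (!nrow(junctions)) {
    junctions$gene1 <- character()
    junctions$gene2 <- character()
    junctions$cancer_gene <- logical()
    return(junctions)
  }
  junctions$gene1 <- gene_hits(genome, junctions$chrom1, junctions$pos1)
  junctions$gene2 <- gene_hits(genome, junctions$chrom2, junctions$pos2)
  hit <- function(g) {
    vapply(strsplit(ifelse(is.na(g), "", g), ","), function(x)
      any(x %in% genome$cancer_genes), logical(1))
  }
  junctions$cancer_gene <- hit(junctions$gene1) | hit(junctions$gene2)
  junctions
}
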