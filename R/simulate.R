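#' Simulation configuration
#'
#' Parameters of the synthetic clone-phylogeny data generator. Defaults
#' emulate the statistical structure of laser-capture micro-dissected
#' mate-pair sequencing of mixed germ cell tumours: a handful of germline
#' junctions per patient present in every component, true somatic junctions
#' with supporting-fragment counts of at least 7 (shifted negative binomial),
#' sporadic false calls with support below the quality threshold, arm-level
#' aneuploidy with a universal multi-copy 12p gain in invasive components,
#' and exome-style SNP allele fractions with whole-chromosome copy-neutral
#' LOH.
#'
#' @param seed integer RNG seed (`NULL` = use the current RNG state).
#' @param n_patients cohort size used by [run_simulated_cohort()].
#' @param germline_junctions_per_patient germline junctions present in every
#'   component of a patient, including the normal.
#' @param false_junction_rate expected false junction calls per sample; false
#'   calls get supporting counts uniform on 1..6, below the quality threshold.
#' @param support_mu,support_size mean and size of the negative binomial whose
#'   draw is added to the floor of 7 to give true-junction support.
#' @param breakpoint_jitter_sd per-sample Gaussian jitter (bp, sd) applied to
#'   emitted breakpoint positions, emulating breakpoint-estimation scatter
#'   between samples.
#' @param depth_per_bin mean read count per copy-number bin at 2N.
#' @param depth_noise extra dispersion of bin counts (0 = Poisson; > 0 =
#'   negative binomial with size `1/depth_noise`).
#' @param bins_per_arm read-depth bins per chromosome arm.
#' @param snp_density heterozygous SNP sites per Mb (ascertained in the
#'   normal).
#' @param snp_depth mean sequencing depth per SNP site.
#' @param mut_depth_mean mean exome coverage of mutation sites.
#' @param fragment_size_mean,fragment_size_sd mate-pair fragment size model in
#'   bp (mean 3700 for a typical mate-pair library).
#' @param i12p_gain_level integer copy state (3-5) of chromosome arm 12p in
#'   invasive components.
#' @param type_mix named probabilities of junction classes
#'   (translocation/deletion/inversion).
#' @param intra_size_meanlog,intra_size_sdlog,intra_size_min lognormal size
#'   model (bp) for intrachromosomal junctions, truncated below at
#'   `intra_size_min` so true events clear the small-polymorphism size filter.
#' @param n_background_fragments concordant background fragments emitted by
#'   [simulate_fragments()].
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = NULL,
                       n_patients = 10,
                       germline_junctions_per_patient = 5,
                       false_junction_rate = 2,
                       support_mu = 8, support_size = 3,
                       breakpoint_jitter_sd = 500,
                       depth_per_bin = 100, depth_noise = 0,
                       bins_per_arm = 50,
                       snp_density = 5, snp_depth = 100,
                       mut_depth_mean = 60,
                       fragment_size_mean = 3700, fragment_size_sd = 370,
                       i12p_gain_level = 4,
                       type_mix = c(translocation = 0.55, deletion = 0.25,
                                    inversion = 0.20),
                       intra_size_meanlog = log(2.8e5),
                       intra_size_sdlog = 1,
                       intra_size_min = 1.1e5,
                       n_background_fragments = 1000) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_patients, cfg$germline_junctions_per_patient,
              cfg$false_junction_rate, cfg$depth_per_bin, cfg$snp_density,
              cfg$snp_depth, cfg$bins_per_arm, cfg$n_background_fragments)
  if (any(counts < 0)) stop_input("all counts and rates must be >= 0")
  if (!cfg$i12p_gain_level %in% 3:5)
    stop_input("i12p_gain_level must be 3, 4 or 5")
  if (cfg$fragment_size_mean <= 0) stop_input("fragment_size_mean must be > 0")
  stopifnot(abs(sum(type_mix) - 1) < 1e-8)
  class(cfg) <- "sim_config"
  cfg
}

## True-junction supporting-fragment counts: floor of 7 plus a negative
## binomial tail, so all true junctions clear the quality threshold.
draw_support <- function(n, config) {
  7 + stats::rnbinom(n, size = config$support_size, mu = config$support_mu)
}

## Random junctions of the configured class mix; positions uniform, sizes of
## intrachromosomal events lognormal truncated at intra_size_min.
simulate_junction_positions <- function(n, genome, config, ids = NULL,
                                        origin = NA_character_) {
  if (n == 0) return(junction_table())
  ch <- genome$chromosomes
  type <- sample(names(config$type_mix), n, replace = TRUE,
                 prob = config$type_mix)
  chrom1 <- chrom2 <- character(n)
  pos1 <- pos2 <- numeric(n)
  strand1 <- strand2 <- character(n)
  wt <- ch$length / sum(ch$length)
  for (i in seq_len(n)) {
    if (type[i] == "translocation") {
      cs <- sample(ch$name, 2, prob = wt)
      chrom1[i] <- cs[1]; chrom2[i] <- cs[2]
      pos1[i] <- floor(stats::runif(1, 1e4, ch$length[ch$name == cs[1]] - 1e4))
      pos2[i] <- floor(stats::runif(1, 1e4, ch$length[ch$name == cs[2]] - 1e4))
      st <- sample(c("+", "-"), 2, replace = TRUE)
      strand1[i] <- st[1]; strand2[i] <- st[2]
    } else {
      cc <- sample(ch$name, 1, prob = wt)
      len <- ch$length[ch$name == cc]
      size <- max(config$intra_size_min,
                  stats::rlnorm(1, config$intra_size_meanlog,
                                config$intra_size_sdlog))
      size <- min(size, 0.4 * len)
      chrom1[i] <- chrom2[i] <- cc
      pos1[i] <- floor(stats::runif(1, 1e4, len - size - 1e4))
      pos2[i] <- pos1[i] + round(size)
      if (type[i] == "deletion") {
        strand1[i] <- "+"; strand2[i] <- "-"
      } else {
        st <- sample(c("+", "-"), 1)
        strand1[i] <- strand2[i] <- st
      }
    }
  }
  junction_table(chrom1, pos1, strand1, chrom2, pos2, strand2,
                 support = rep(7, n), id = ids, type = type,
                 origin = rep(origin, n))
}

## Per-sample re-observation of a truth junction table: support redrawn,
## breakpoints jittered, clamped to chromosome bounds.
observe_junctions <- function(truth, genome, config) {
  if (!nrow(truth)) return(truth)
  truth$support <- draw_support(nrow(truth), config)
  if (config$breakpoint_jitter_sd > 0) {
    lens <- genome$chromosomes$length
    names(lens) <- genome$chromosomes$name
    jit <- function(pos, chrom) {
      p <- round(pos + stats::rnorm(length(pos), 0, config$breakpoint_jitter_sd))
      pmin(pmax(p, 1), lens[chrom] - 1)
    }
    truth$pos1 <- unname(jit(truth$pos1, truth$chrom1))
    truth$pos2 <- unname(jit(truth$pos2, truth$chrom2))
    truth <- canonicalize_junctions(truth)
  }
  truth
}

#' Simulate read-depth bins for a karyotype
#'
#' Emits `bins_per_arm` equal-width bins per chromosome arm with counts drawn
#' around `depth_per_bin * state / 2`, Poisson by default or negative binomial
#' when `dispersion > 0`.
#'
#' @param genome a [genome_model()].
#' @param arm_states named numeric vector of integer copy states per arm
#'   (missing arms default to 2).
#' @param depth_per_bin mean count per bin at 2N.
#' @param bins_per_arm bins per arm.
#' @param dispersion extra-Poisson dispersion (negative binomial size
#'   `1/dispersion`).
#' @param sample_id identifier attached to the profile.
#' @return A `depth_profile`: data.frame (`chrom`, `start`, `end`, `count`)
#'   with the sample id as an attribute.
#' @export
simulate_depth_profile <- function(genome, arm_states = NULL,
                                   depth_per_bin = 100, bins_per_arm = 50,
                                   dispersion = 0, sample_id = "S1") {
  arms <- chrom_arms(genome)
  states <- stats::setNames(rep(2, nrow(arms)), arms$arm)
  if (!is.null(arm_states)) states[names(arm_states)] <- arm_states
  out <- do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
    br <- round(seq(arms$start[i], arms$end[i], length.out = bins_per_arm + 1))
    mu <- depth_per_bin * states[arms$arm[i]] / 2
    n <- length(br) - 1
    cnt <- if (dispersion > 0)
      stats::rnbinom(n, size = 1 / dispersion, mu = mu)
    else stats::rpois(n, mu)
    data.frame(chrom = arms$chrom[i], start = br[-length(br)], end = br[-1],
               count = cnt)
  }))
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  structure(out, sample_id = sample_id,
            class = c("depth_profile", "data.frame"))
}

#' Heterozygous SNP site positions for a patient
#'
#' @param genome a [genome_model()].
#' @param snp_density sites per Mb.
#' @return data.frame (`chrom`, `pos`), sorted.
#' @export
simulate_het_sites <- function(genome, snp_density = 5) {
  ch <- genome$chromosomes
  do.call(rbind, lapply(seq_len(nrow(ch)), function(i) {
    n <- round(snp_density * ch$length[i] / 1e6)
    data.frame(chrom = ch$name[i],
               pos = sort(floor(stats::runif(n, 1, ch$length[i]))))
  }))
}

#' Simulate SNP allele counts for one sample
#'
#' At sites heterozygous in the matched normal, the expected reference-allele
#' fraction follows the allele dosage implied by the chromosome's copy state:
#' 0.5 at 2N heterozygous, 0 or 1 per site under copy-neutral LOH (one
#' homolog duplicated), and `a/s` with `a` in `{1, s-1}` on arms at state
#' `s != 2` (one homolog gained or lost).
#'
#' @param genome a [genome_model()].
#' @param sites data.frame (`chrom`, `pos`) of het sites (from
#'   [simulate_het_sites()]).
#' @param arm_states named copy states per arm (missing = 2).
#' @param cnloh_chroms chromosomes carrying whole-chromosome copy-neutral LOH.
#' @param snp_depth mean depth per site (Poisson, floored at 1).
#' @param sample_id identifier.
#' @param normal if TRUE all sites are balanced heterozygous regardless of
#'   states.
#' @return An `allele_profile`: data.frame (`chrom`, `pos`, `ref_count`,
#'   `alt_count`) with `sample_id` and `het_sites_from_normal` attributes.
#' @export
simulate_allele_profile <- function(genome, sites, arm_states = NULL,
                                    cnloh_chroms = character(),
                                    snp_depth = 100, sample_id = "S1",
                                    normal = FALSE) {
  arms <- chrom_arms(genome)
  states <- stats::setNames(rep(2, nrow(arms)), arms$arm)
  if (!is.null(arm_states)) states[names(arm_states)] <- arm_states
  n <- nrow(sites)
  depth <- pmax(1, stats::rpois(n, snp_depth))
  if (normal) {
    p <- rep(0.5, n)
  } else {
    s <- states[arm_of(genome, sites$chrom, sites$pos)]
    p <- rep(0.5, n)
    loh <- sites$chrom %in% cnloh_chroms
    p[loh] <- sample(c(0, 1), sum(loh), replace = TRUE)
    ab <- !loh & s != 2
    if (any(ab)) {
      sa <- s[ab]
      a <- ifelse(stats::rbinom(sum(ab), 1, 0.5) == 1, pmax(sa - 1, 0),
                  pmin(1, sa))
      p[ab] <- ifelse(sa > 0, a / sa, 0.5)
    }
  }
  ref <- stats::rbinom(n, depth, p)
  out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    ref_count = ref, alt_count = depth - ref)
  structure(out, sample_id = sample_id, het_sites_from_normal = TRUE,
            class = c("allele_profile", "data.frame"))
}

## one random coding mutation table row per draw, placed inside gene regions
simulate_mutations <- function(n, genome, config, ids,
                               consequences = NULL) {
  if (n == 0)
    return(data.frame(id = character(), chrom = character(), pos = numeric(),
                      ref = character(), alt = character(), gene = character(),
                      consequence = character(), stringsAsFactors = FALSE))
  g <- genome$genes[sample(nrow(genome$genes), n, replace = TRUE), ]
  pos <- floor(stats::runif(n, g$start, g$end - 1))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  if (is.null(consequences))
    consequences <- sample(c("missense", "nonsense", "frameshift", "splice"),
                           n, replace = TRUE, prob = c(0.6, 0.15, 0.15, 0.1))
  data.frame(id = ids, chrom = g$chrom, pos = pos, ref = ref, alt = unname(alt),
             gene = g$gene, consequence = consequences,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate one patient's multi-component dataset
#'
#' Generates, for every sampled clone of the phylogeny plus (optionally) a
#' matched normal: a junction call set, a binned read-depth profile, a SNP
#' allele-fraction profile and a somatic mutation table — together with a
#' ground-truth record of everything that was planted. Somatic events
#' accumulate along root-to-node paths, so any component inherits all events
#' of its ancestors; germline junctions appear in every component including
#' the normal; invasive (non-GCNIS, non-normal) components carry the 12p gain
#' at `config$i12p_gain_level`; false junctions are appended with support
#' drawn uniformly on 1..6.
#'
#' @param config a [sim_config()].
#' @param genome a [genome_model()].
#' @param phylogeny a [clone_phylogeny()].
#' @param patient_id identifier used to prefix sample ids.
#' @param components node ids to emit as samples (default: all non-root
#'   nodes).
#' @param include_normal emit a normal-tissue sample from the root clone.
#'
#' @return A list of class `patient_simulation` with elements `call_sets`,
#'   `depth_profiles`, `allele_profiles`, `mutation_tables` (named by sample
#'   id) and `truth`.
#' @export
simulate_patient <- function(config, genome, phylogeny, patient_id = "P1",
                             components = NULL, include_normal = TRUE) {
  stopifnot(inherits(config, "sim_config"), inherits(genome, "genome_model"),
            inherits(phylogeny, "clone_phylogeny"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(components))
    components <- setdiff(phylogeny$nodes$id, phylogeny$root)
  if (!all(components %in% phylogeny$nodes$id))
    stop_input("unknown component node(s)")

  arms <- chrom_arms(genome)
  autosomes <- grep("chr[0-9]+$", genome$chromosomes$name, value = TRUE)

  ## -- germline junctions, present everywhere --------------------------------
  germline <- simulate_junction_positions(
    config$germline_junctions_per_patient, genome, config,
    ids = sprintf("%s_gl%02d", patient_id,
                  seq_len(config$germline_junctions_per_patient)),
    origin = "germline")

  ## -- walk edges root-down, accumulating clone state ------------------------
  e <- phylogeny$edges
  topo <- character()
  frontier <- phylogeny$root
  while (length(frontier)) {
    kids <- e$child[e$parent %in% frontier]
    topo <- c(topo, kids)
    frontier <- kids
  }
  clone <- list()
  clone[[phylogeny$root]] <- list(
    junctions = junction_table(),
    states = stats::setNames(rep(2, nrow(arms)), arms$arm),
    cnloh = character(),
    mutations = simulate_mutations(0, genome, config, character()))
  mut_counter <- 0
  for (child in topo) {
    i <- which(e$child == child)
    parent <- clone[[e$parent[i]]]
    st <- parent$states
    loh <- parent$cnloh
    ## arm-level copy events (chr12 reserved for the i12p rule, cnLOH
    ## chromosomes kept copy-neutral so truth labels stay unambiguous)
    ncnv <- e$cnvs[i]
    if (ncnv > 0) {
      cand <- arms$arm[arms$chrom %in% setdiff(autosomes, c("chr12", loh))]
      pick <- sample(cand, min(ncnv, length(cand)))
      delta <- sample(c(1, -1), length(pick), replace = TRUE,
                      prob = c(0.6, 0.4))
      st[pick] <- pmin(5, pmax(1, st[pick] + delta))
    }
    hist_child <- phylogeny$nodes$histology[phylogeny$nodes$id == child]
    if (is_invasive_histology(hist_child)) {
      st["12p"] <- config$i12p_gain_level
    }
    ## whole-chromosome copy-neutral LOH on currently 2N/2N autosomes
    nloh <- e$cnloh[i]
    if (nloh > 0) {
      ok <- vapply(setdiff(autosomes, c("chr12", loh)), function(cc) {
        all(st[arms$arm[arms$chrom == cc]] == 2)
      }, logical(1))
      cand <- names(ok)[ok]
      loh <- c(loh, sample(cand, min(nloh, length(cand))))
    }
    nj <- e$junctions[i]
    jt <- simulate_junction_positions(
      nj, genome, config,
      ids = if (nj) sprintf("%s_%s_j%02d", patient_id, child, seq_len(nj))
            else character(),
      origin = child)
    nm <- e$mutations[i]
    mt <- simulate_mutations(
      nm, genome, config,
      ids = if (nm) sprintf("%s_m%03d", patient_id, mut_counter + seq_len(nm))
            else character())
    mut_counter <- mut_counter + nm
    clone[[child]] <- list(junctions = rbind(parent$junctions, jt),
                           states = st, cnloh = loh,
                           mutations = rbind(parent$mutations, mt))
  }

  ## -- shared het SNP sites (ascertained in the normal) ----------------------
  sites <- simulate_het_sites(genome, config$snp_density)

  emit <- components
  if (include_normal) emit <- c(phylogeny$root, emit)
  call_sets <- list(); depth_profiles <- list(); allele_profiles <- list()
  mutation_tables <- list(); truth_junctions <- list()
  truth_states <- list(); truth_cnloh <- list(); truth_mutations <- list()
  meta <- data.frame(sample_id = character(), node = character(),
                     histology = character(), is_normal = logical())

  for (node in emit) {
    hist <- phylogeny$nodes$histology[phylogeny$nodes$id == node]
    sid <- paste(patient_id, node, sep = "_")
    cl <- clone[[node]]
    truth_jt <- rbind(germline, cl$junctions)
    obs <- observe_junctions(truth_jt, genome, config)
    nf <- stats::rpois(1, config$false_junction_rate)
    false_jt <- simulate_junction_positions(
      nf, genome, config,
      ids = if (nf) sprintf("%s_false%02d", sid, seq_len(nf)) else character(),
      origin = "false")
    if (nf) false_jt$support <- sample(1:6, nf, replace = TRUE)
    jt <- rbind(obs, false_jt)
    call_sets[[sid]] <- call_set(sid, patient_id, hist, jt,
                                 is_normal = node == phylogeny$root)
    depth_profiles[[sid]] <- simulate_depth_profile(
      genome, cl$states, config$depth_per_bin, config$bins_per_arm,
      config$depth_noise, sample_id = sid)
    allele_profiles[[sid]] <- simulate_allele_profile(
      genome, sites, cl$states, cl$cnloh, config$snp_depth, sample_id = sid,
      normal = node == phylogeny$root)
    ## emitted mutation table: true coding mutations at good coverage, plus
    ## private non-impacting / low-coverage noise rows not in the truth
    tm <- cl$mutations
    emt <- tm
    if (nrow(emt)) {
      emt$depth_normal <- pmax(20, stats::rpois(nrow(emt), config$mut_depth_mean))
      emt$depth_tumour <- pmax(20, stats::rpois(nrow(emt), config$mut_depth_mean))
    } else {
      emt$depth_normal <- numeric(); emt$depth_tumour <- numeric()
    }
    nn <- stats::rpois(1, 3)
    if (nn > 0 && node != phylogeny$root) {
      noise <- simulate_mutations(
        nn, genome, config, ids = sprintf("%s_noise%02d", sid, seq_len(nn)),
        consequences = sample(c("synonymous", "intronic", "UTR"), nn,
                              replace = TRUE))
      noise$depth_normal <- pmax(20, stats::rpois(nn, config$mut_depth_mean))
      noise$depth_tumour <- pmax(20, stats::rpois(nn, config$mut_depth_mean))
      lowcov <- simulate_mutations(1, genome, config,
                                   ids = sprintf("%s_lowcov", sid))
      lowcov$depth_normal <- sample(5:19, 1)
      lowcov$depth_tumour <- pmax(20, stats::rpois(1, config$mut_depth_mean))
      emt <- rbind(emt, noise, lowcov)
    }
    mutation_tables[[sid]] <- emt
    truth_junctions[[sid]] <- truth_jt
    truth_states[[sid]] <- cl$states
    truth_cnloh[[sid]] <- cl$cnloh
    truth_mutations[[sid]] <- tm
    meta <- rbind(meta, data.frame(sample_id = sid, node = node,
                                   histology = hist,
                                   is_normal = node == phylogeny$root))
  }

  truth <- list(patient_id = patient_id, phylogeny = phylogeny, meta = meta,
                germline = germline, junctions = truth_junctions,
                arm_states = truth_states, cnloh = truth_cnloh,
                mutations = truth_mutations)
  structure(list(call_sets = call_sets, depth_profiles = depth_profiles,
                 allele_profiles = allele_profiles,
                 mutation_tables = mutation_tables, truth = truth),
            class = "patient_simulation")
}

#' Simulate mate-pair fragments for a call set
#'
#' For every junction of the sample, emits a number of discordant fragments
#' equal to its supporting count; each fragment end sits within the
#' fragment-size scale of the true breakpoint, on the side the breakpoint
#' orientation implies (upstream of a `+` breakpoint, downstream of a `-`
#' one), so the orientation-aware innermost fragment end recovers the
#' breakpoint. Concordant background fragments (proper `+`/`-` pairs spanning
#' approximately the library fragment size) are added genome-wide.
#'
#' @param sample a [call_set()].
#' @param config a [sim_config()].
#' @param genome a [genome_model()].
#' @param jitter maximal distance (bp) of a fragment end from its breakpoint;
#'   default half the mean fragment size.
#' @return data.frame of fragments (`chrom1`, `pos1`, `strand1`, `chrom2`,
#'   `pos2`, `strand2`, `sample_id`).
#' @export
simulate_fragments <- function(sample, config, genome,
                               jitter = config$fragment_size_mean / 2) {
  stopifnot(inherits(sample, "call_set"))
  j <- sample$junctions
  lens <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
  if (nrow(j)) {
    bad <- !(j$chrom1 %in% names(lens)) | !(j$chrom2 %in% names(lens)) |
      j$pos1 < 0 | j$pos2 < 0 |
      j$pos1 >= lens[j$chrom1] | j$pos2 >= lens[j$chrom2]
    if (any(bad)) stop_input("junction breakpoint outside genome bounds")
  }
  disc <- NULL
  if (nrow(j)) {
    rep_i <- rep(seq_len(nrow(j)), times = j$support)
    n <- length(rep_i)
    off1 <- floor(stats::runif(n, 0, jitter + 1e-9))
    off2 <- floor(stats::runif(n, 0, jitter + 1e-9))
    p1 <- ifelse(j$strand1[rep_i] == "+", j$pos1[rep_i] - off1,
                 j$pos1[rep_i] + off1)
    p2 <- ifelse(j$strand2[rep_i] == "+", j$pos2[rep_i] - off2,
                 j$pos2[rep_i] + off2)
    disc <- data.frame(chrom1 = j$chrom1[rep_i],
                       pos1 = pmin(pmax(p1, 0), lens[j$chrom1[rep_i]] - 1),
                       strand1 = j$strand1[rep_i],
                       chrom2 = j$chrom2[rep_i],
                       pos2 = pmin(pmax(p2, 0), lens[j$chrom2[rep_i]] - 1),
                       strand2 = j$strand2[rep_i])
  }
  nb <- config$n_background_fragments
  conc <- NULL
  if (nb > 0) {
    ch <- genome$chromosomes
    cc <- sample(ch$name, nb, replace = TRUE, prob = ch$length)
    span <- pmax(100, round(stats::rnorm(nb, config$fragment_size_mean,
                                         config$fragment_size_sd)))
    start <- floor(stats::runif(nb, 0, lens[cc] - span - 1))
    conc <- data.frame(chrom1 = cc, pos1 = start, strand1 = "+",
                       chrom2 = cc, pos2 = start + span, strand2 = "-")
  }
  out <- rbind(disc, conc)
  if (is.null(out))
    out <- data.frame(chrom1 = character(), pos1 = numeric(),
                      strand1 = character(), chrom2 = character(),
                      pos2 = numeric(), strand2 = character())
  out <- canonicalize_junctions(out)
  out$sample_id <- rep(sample$sample_id, nrow(out))
  rownames(out) <- NULL
  out
}
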