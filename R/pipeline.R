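#' Run the full per-patient analysis
#'
#' Orchestrates the analysis stages for one patient: junction filtering with
#' cross-sample rescue, germline subtraction against the normal component
#' (when present), shared/unique lineage matrix and dendrogram, arm-level
#' karyotyping with 12p-gain detection and cross-component comparison, and —
#' when exome-style inputs are given — cnLOH calling, mutation filtering and
#' pairwise shared-mutation counts. All stages are pure functions of the
#' inputs, so reruns are reproducible; when `out_dir` is given every
#' intermediate artefact is written as plain text along with a run manifest.
#'
#' @param call_sets named list of [call_set()]s for one patient (junction
#'   call sets per component, the normal included if available).
#' @param genome a [genome_model()].
#' @param depth_profiles optional named list of depth profiles (same names).
#' @param allele_profiles optional named list of allele profiles.
#' @param mutation_tables optional named list of mutation tables.
#' @param config a [filter_config()].
#' @param out_dir optional output directory (created if missing).
#' @param seed optional integer recorded in the manifest.
#' @return A list of class `patient_result` with elements `patient_id`,
#'   `filtered`, `somatic`, `lineage`, `dendrogram` (NULL with < 2 tumour
#'   components), `karyotypes`, `cnv_comparison`, `i12p`, `cnloh`,
#'   `mutations`, `shared_mutation_counts`.
#' @export
run_patient <- function(call_sets, genome, depth_profiles = NULL,
                        allele_profiles = NULL, mutation_tables = NULL,
                        config = filter_config(), out_dir = NULL,
                        seed = NULL) {
  if (!length(call_sets)) stop_input("no call sets given")
  pid <- unique(vapply(call_sets, `[[`, "", "patient_id"))
  if (length(pid) != 1) stop_input("call sets span multiple patients")
  is_norm <- vapply(call_sets, `[[`, logical(1), "is_normal")
  if (all(is_norm)) stop_input("patient ", pid, " has no tumour component")

  ## 1. quality/size/genic filtering with cross-sample rescue
  filtered <- lapply(seq_along(call_sets), function(i)
    filter_sample(call_sets[[i]], call_sets[-i], config, genome))
  names(filtered) <- names(call_sets)

  ## 2. germline subtraction
  normal <- if (any(is_norm)) filtered[[which(is_norm)[1]]] else NULL
  tumours <- filtered[!is_norm]
  somatic <- lapply(tumours, subtract_germline, normal = normal,
                    tolerance = config$match_tolerance)

  ## 3. lineage
  lineage <- shared_unique_matrix(somatic, config$match_tolerance)
  dendro <- if (length(somatic) >= 2)
    build_dendrogram(somatic, config$match_tolerance) else NULL

  ## 4. copy number
  karyotypes <- NULL; cnv_cmp <- NULL; i12p <- NULL
  if (!is.null(depth_profiles)) {
    karyotypes <- lapply(depth_profiles, call_arm_states, genome = genome)
    if (length(karyotypes) >= 2)
      cnv_cmp <- compare_karyotypes(karyotypes)
    i12p <- do.call(rbind, lapply(names(karyotypes), function(s) {
      d <- detect_i12p(karyotypes[[s]])
      data.frame(sample_id = s, state_12p = d$state, gain_12p = d$gain)
    }))
  }

  ## 5. cnLOH and mutations
  cnloh <- NULL
  if (!is.null(allele_profiles) && !is.null(karyotypes)) {
    tum_ids <- intersect(names(allele_profiles), names(tumours))
    cnloh <- lapply(tum_ids, function(s)
      call_cnloh(allele_profiles[[s]], karyotypes[[s]]))
    names(cnloh) <- tum_ids
  }
  muts <- NULL; shared_mut <- NULL
  if (!is.null(mutation_tables)) {
    tum_ids <- intersect(names(mutation_tables), names(tumours))
    muts <- lapply(mutation_tables[tum_ids], filter_mutations)
    if (length(muts) >= 2) {
      cmb <- utils::combn(length(muts), 2)
      shared_mut <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
        i <- cmb[1, k]; j <- cmb[2, k]
        data.frame(sample_a = names(muts)[i], sample_b = names(muts)[j],
                   shared = nrow(shared_mutations(muts[[i]], muts[[j]])))
      }))
    }
  }

  res <- structure(list(patient_id = pid, filtered = filtered,
                        somatic = somatic, lineage = lineage,
                        dendrogram = dendro, karyotypes = karyotypes,
                        cnv_comparison = cnv_cmp, i12p = i12p, cnloh = cnloh,
                        mutations = muts,
                        shared_mutation_counts = shared_mut),
                   class = "patient_result")
  if (!is.null(out_dir)) write_patient_result(res, out_dir, config, seed)
  res
}

write_patient_result <- function(res, out_dir, config, seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  p <- function(...) file.path(out_dir, paste0(...))
  for (s in names(res$somatic)) {
    f <- p(s, ".somatic.bedpe")
    write_junction_bedpe(res$somatic[[s]]$junctions, f)
    files <- c(files, basename(f))
  }
  if (nrow(res$lineage$pairs)) {
    write_tsv_file(res$lineage$pairs, p("lineage_matrix.tsv"))
    files <- c(files, "lineage_matrix.tsv")
  }
  if (!is.null(res$dendrogram)) {
    writeLines(res$dendrogram$newick, p("dendrogram.nwk"))
    files <- c(files, "dendrogram.nwk")
  }
  if (!is.null(res$karyotypes)) {
    for (s in names(res$karyotypes)) {
      f <- p(s, ".arm_states.tsv")
      write_arm_states_tsv(res$karyotypes[[s]], f)
      files <- c(files, basename(f))
    }
  }
  if (!is.null(res$cnv_comparison)) {
    write_tsv_file(res$cnv_comparison, p("cnv_comparison.tsv"))
    files <- c(files, "cnv_comparison.tsv")
  }
  if (!is.null(res$i12p)) {
    write_tsv_file(res$i12p, p("i12p.tsv"))
    files <- c(files, "i12p.tsv")
  }
  if (!is.null(res$cnloh)) {
    for (s in names(res$cnloh)) {
      f <- p(s, ".cnloh.tsv")
      write_tsv_file(res$cnloh[[s]], f)
      files <- c(files, basename(f))
    }
  }
  if (!is.null(res$shared_mutation_counts)) {
    write_tsv_file(res$shared_mutation_counts, p("shared_mutations.tsv"))
    files <- c(files, "shared_mutations.tsv")
  }
  manifest <- list(
    package = "svlineage",
    version = as.character(utils::packageVersion("svlineage")),
    patient_id = res$patient_id,
    seed = seed,
    filter_config = unclass(config),
    files = sort(files))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(res)
}

#' Simulate and analyse a synthetic cohort
#'
#' For each patient, draws one of the canonical evolution-model phylogenies
#' ([phylogeny_model()]), samples 3-4 components plus a normal, simulates the
#' patient with [simulate_patient()] and runs [run_patient()]. Per-patient
#' seeds are derived deterministically from `seed`, so the whole cohort is a
#' pure function of the configuration and seed.
#'
#' @param config a [sim_config()].
#' @param genome a [genome_model()].
#' @param n_patients number of patients (default `config$n_patients`).
#' @param out_dir optional output directory; per-patient artefacts go into
#'   subdirectories.
#' @param seed master seed (default `config$seed`, or 1).
#' @param filter_cfg a [filter_config()].
#' @return List of class `cohort_result`: `patients` (named list of
#'   `patient_result`), `simulations` (named list of `patient_simulation`)
#'   and `summary` (a [cohort_summary()] over all somatic sets).
#' @export
run_simulated_cohort <- function(config = sim_config(), genome = toy_genome(),
                                 n_patients = config$n_patients,
                                 out_dir = NULL, seed = config$seed,
                                 filter_cfg = filter_config()) {
  if (is.null(seed)) seed <- 1
  patients <- list(); sims <- list()
  for (i in seq_len(n_patients)) {
    set.seed(derive_seed(seed, i))
    pid <- sprintf("P%02d", i)
    model <- sample(c("direct", "linear"), 1)
    phy <- phylogeny_model(model)
    tumour_nodes <- setdiff(phy$nodes$id, "normal")
    k <- sample(3:min(4, length(tumour_nodes)), 1)
    comp <- sample_components(phy, tumour_nodes, k)
    cfg_i <- config
    cfg_i$seed <- NULL  # RNG already seeded; keep one stream per patient
    sim <- simulate_patient(cfg_i, genome, phy, patient_id = pid,
                            components = comp, include_normal = TRUE)
    od <- if (!is.null(out_dir)) file.path(out_dir, pid) else NULL
    patients[[pid]] <- run_patient(sim$call_sets, genome,
                                   sim$depth_profiles, sim$allele_profiles,
                                   sim$mutation_tables, filter_cfg,
                                   out_dir = od, seed = derive_seed(seed, i))
    sims[[pid]] <- sim
  }
  all_somatic <- unlist(lapply(patients, `[[`, "somatic"), recursive = FALSE)
  summary <- cohort_summary(all_somatic)
  res <- structure(list(patients = patients, simulations = sims,
                        summary = summary), class = "cohort_result")
  if (!is.null(out_dir)) {
    write_tsv_file(summary$per_histology,
                   file.path(out_dir, "cohort_histology_summary.tsv"))
  }
  res
}

## components are sampled connected-from-the-top so that ancestors of any
## sampled invasive node are represented where possible
sample_components <- function(phy, tumour_nodes, k) {
  depth <- vapply(tumour_nodes, function(n) length(path_edges(phy, n)),
                  integer(1))
  ord <- tumour_nodes[order(depth, tumour_nodes)]
  picked <- character()
  pool <- ord
  while (length(picked) < k && length(pool)) {
    w <- 2^(-(seq_along(pool) - 1))  # favour shallow nodes
    nxt <- sample(pool, 1, prob = w)
    picked <- c(picked, nxt)
    pool <- setdiff(pool, nxt)
  }
  sort(picked)
}
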