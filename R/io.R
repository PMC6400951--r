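## All files are plain TSV, 0-based half-open coordinates, written with a
## fixed format so that reruns with the same seed are byte-identical.

write_tsv_file <- function(df, path, col.names = TRUE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = col.names, na = ".")
  invisible(path)
}

#' Read and write junction BEDPE
#'
#' Standard 10-column BEDPE: `chrom1 start1 end1 chrom2 start2 end2 name
#' score strand1 strand2`, 0-based half-open; breakpoints are single
#' positions (`end = start + 1`), `name` the junction id and `score` the
#' supporting-fragment count.
#'
#' @param junctions a [junction_table()].
#' @param path file path.
#' @return `write_junction_bedpe()`: the path, invisibly;
#'   `read_junction_bedpe()`: a [junction_table()].
#' @export
write_junction_bedpe <- function(junctions, path) {
  df <- data.frame(chrom1 = junctions$chrom1, start1 = junctions$pos1,
                   end1 = junctions$pos1 + 1,
                   chrom2 = junctions$chrom2, start2 = junctions$pos2,
                   end2 = junctions$pos2 + 1,
                   name = junctions$id, score = junctions$support,
                   strand1 = junctions$strand1, strand2 = junctions$strand2)
  write_tsv_file(format_numeric(df), path, col.names = FALSE)
}

#' @rdname write_junction_bedpe
#' @export
read_junction_bedpe <- function(path) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "name", "score", "strand1", "strand2")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = cols,
                          colClasses = c("character", "numeric", "numeric",
                                         "character", "numeric", "numeric",
                                         "character", "numeric", "character",
                                         "character"))
  junction_table(df$chrom1, df$start1, df$strand1, df$chrom2, df$start2,
                 df$strand2, support = df$score, id = df$name)
}

## avoid scientific notation creeping into coordinate columns
format_numeric <- function(df) {
  for (i in seq_along(df)) {
    if (is.numeric(df[[i]])) df[[i]] <- format(df[[i]], scientific = FALSE,
                                               trim = TRUE)
  }
  df
}

#' Read and write binned read-depth tables (BED + value)
#'
#' Four columns: `chrom start end count`, 0-based half-open.
#'
#' @param profile a depth profile data.frame.
#' @param path file path.
#' @param sample_id sample id attached on read.
#' @return The path / a `depth_profile` data.frame.
#' @export
write_depth_bed <- function(profile, path) {
  write_tsv_file(format_numeric(as.data.frame(profile)), path,
                 col.names = FALSE)
}

#' @rdname write_depth_bed
#' @export
read_depth_bed <- function(path, sample_id = NA_character_) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "count"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  structure(df, sample_id = sample_id,
            class = c("depth_profile", "data.frame"))
}

#' Read and write SNP allele-count tables
#'
#' Columns: `chrom pos ref_count alt_count` (position 0-based).
#'
#' @param profile an allele profile data.frame.
#' @param path file path.
#' @param sample_id sample id attached on read.
#' @return The path / an `allele_profile` data.frame.
#' @export
write_allele_tsv <- function(profile, path) {
  write_tsv_file(format_numeric(as.data.frame(profile)), path)
}

#' @rdname write_allele_tsv
#' @export
read_allele_tsv <- function(path, sample_id = NA_character_) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  structure(df, sample_id = sample_id, het_sites_from_normal = TRUE,
            class = c("allele_profile", "data.frame"))
}

#' Read and write mutation tables
#'
#' VCF-like TSV with columns `chrom pos ref alt gene consequence
#' depth_normal depth_tumour` (position 0-based; an `id` column is kept when
#' present).
#'
#' @param muts mutation data.frame.
#' @param path file path.
#' @return The path / a data.frame.
#' @export
write_mutation_tsv <- function(muts, path) {
  write_tsv_file(format_numeric(as.data.frame(muts)), path)
}

#' @rdname write_mutation_tsv
#' @export
read_mutation_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write per-arm copy states
#'
#' @param karyotype an `arm_karyotype`.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_arm_states_tsv <- function(karyotype, path) {
  df <- data.frame(arm = names(karyotype$states),
                   state = unname(karyotype$states),
                   median_depth = unname(karyotype$arm_medians),
                   baseline = karyotype$baseline)
  write_tsv_file(df, path)
}

#' Write ground truth as JSON
#'
#' @param truth the `truth` element of a [simulate_patient()] result.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  out <- list(
    patient_id = truth$patient_id,
    meta = truth$meta,
    germline = as.data.frame(truth$germline),
    junctions = lapply(truth$junctions, as.data.frame),
    arm_states = lapply(truth$arm_states, as.list),
    cnloh = truth$cnloh,
    mutations = lapply(truth$mutations, as.data.frame),
    phylogeny = list(nodes = truth$phylogeny$nodes,
                     edges = truth$phylogeny$edges,
                     root = truth$phylogeny$root))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
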