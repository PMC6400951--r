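#' Call arm-level copy-number states from binned read depth
#'
#' Computes the median bin count per chromosome arm, normalizes by a 2N
#' baseline estimated as the modal autosomal arm median (the largest group of
#' autosomal arm medians agreeing within 10%), and rounds `2 * median /
#' baseline` to the nearest integer state (ties to even, capped at 8). Arms
#' whose bins cover less than 80% of the arm are flagged no-call (`NA`)
#' rather than guessed.
#'
#' Whole-arm segmentation reflects the dominant mode of aneuploidy in germ
#' cell tumours — whole-arm or whole-chromosome gains and losses — and makes
#' the modal baseline robust without a matched normal.
#'
#' @param profile a depth profile data.frame (`chrom`, `start`, `end`,
#'   `count`), e.g. from [simulate_depth_profile()] or [read_depth_bed()].
#' @param genome a [genome_model()].
#' @return An object of class `arm_karyotype`: list with `states` (named
#'   integer vector per arm, `NA` = no-call), `baseline` (2N median depth)
#'   and `arm_medians`.
#' @export
call_arm_states <- function(profile, genome) {
  arms <- chrom_arms(genome)
  if (any(profile$count < 0)) stop_input("bin counts must be >= 0")
  mid <- (profile$start + profile$end) / 2
  arm <- arm_of(genome, profile$chrom, mid)
  med <- tapply(profile$count, factor(arm, levels = arms$arm),
                stats::median)
  covered <- tapply(profile$end - profile$start,
                    factor(arm, levels = arms$arm), sum)
  covered[is.na(covered)] <- 0
  frac <- covered / (arms$end - arms$start)
  nocall <- frac < 0.8
  autosomal <- grepl("^[0-9]+[pq]$", arms$arm)
  base_med <- med[autosomal & !nocall & !is.na(med)]
  if (!length(base_med)) stop_input("no callable autosomal arms")
  baseline <- modal_value(as.numeric(base_med), rel_tol = 0.1)
  states <- round(2 * as.numeric(med) / baseline)
  states <- pmin(pmax(states, 0), 8)
  states[nocall] <- NA
  names(states) <- arms$arm
  structure(list(states = states, baseline = baseline,
                 arm_medians = stats::setNames(as.numeric(med), arms$arm)),
            class = "arm_karyotype")
}

## Largest cluster of values agreeing within rel_tol of the cluster centre;
## returns the cluster median. With more than half the arms at 2N this is the
## 2N depth.
modal_value <- function(x, rel_tol = 0.1) {
  x <- sort(x)
  best <- x[1]; best_n <- 0
  for (i in seq_along(x)) {
    grp <- x[abs(x - x[i]) <= rel_tol * x[i]]
    if (length(grp) > best_n) {
      best_n <- length(grp)
      best <- stats::median(grp)
    }
  }
  best
}

#' @export
print.arm_karyotype <- function(x, ...) {
  ab <- x$states[!is.na(x$states) & x$states != 2]
  cat(sprintf("arm_karyotype: baseline %.1f, %d aberrant arms\n",
              x$baseline, length(ab)))
  if (length(ab))
    cat(" ", paste(sprintf("%s=%dN", names(ab), ab), collapse = " "), "\n")
  invisible(x)
}

#' Aberrant arms of a karyotype
#'
#' @param karyotype an `arm_karyotype`.
#' @return data.frame (`arm`, `state`, `call`) of arms with state != 2.
#' @export
arm_calls <- function(karyotype) {
  st <- karyotype$states
  ab <- which(!is.na(st) & st != 2)
  data.frame(arm = names(st)[ab], state = unname(st[ab]),
             call = ifelse(st[ab] > 2, "gain", "loss"), row.names = NULL)
}

#' Compare arm karyotypes across components
#'
#' Classifies every arm across two or more components as `shared-gain` (all
#' states > 2), `shared-loss` (all < 2), `neutral` (all == 2), `discordant`
#' otherwise, or `no-call` when any component has no call for the arm.
#'
#' @param karyotypes named list of `arm_karyotype` objects (>= 2), same
#'   genome model.
#' @return data.frame with one row per arm: per-component states and a
#'   `class` column (the aneuploidy matrix, samples x arms, in long-ish
#'   form).
#' @export
compare_karyotypes <- function(karyotypes) {
  if (length(karyotypes) < 2) stop_input("need >= 2 components to compare")
  arms <- names(karyotypes[[1]]$states)
  for (k in karyotypes) {
    if (!identical(names(k$states), arms))
      stop_input("karyotypes use different genome models")
  }
  st <- vapply(karyotypes, function(k) k$states, numeric(length(arms)))
  if (is.null(dim(st))) st <- matrix(st, nrow = length(arms))
  cls <- apply(st, 1, function(s) {
    if (anyNA(s)) "no-call"
    else if (all(s > 2)) "shared-gain"
    else if (all(s < 2)) "shared-loss"
    else if (all(s == 2)) "neutral"
    else "discordant"
  })
  out <- data.frame(arm = arms, st, class = cls, row.names = NULL,
                    check.names = FALSE)
  names(out)[seq_along(karyotypes) + 1] <- names(karyotypes)
  out
}

#' Detect the multi-copy 12p gain
#'
#' @param karyotype an `arm_karyotype`.
#' @return List with `gain` (TRUE when the 12p state is 3 or more) and
#'   `state` (the integer 12p state, possibly `NA`).
#' @export
detect_i12p <- function(karyotype) {
  s <- karyotype$states["12p"]
  list(gain = !is.na(s) && s >= 3, state = unname(s))
}
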