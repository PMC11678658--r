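# Synthetic FPKM generator: grouped replicate design, log-normal baselines,
# multiplicative planted effects on designated marker classes, and a truth
# table for recovery testing.

#' Specification for a synthetic FPKM study
#'
#' Defaults emulate the study layout the pipeline targets: 11 disease groups
#' (the first 7 neuronopathic) plus one control group, 4 biological replicates
#' per group, and 3000 transcripts of which the large majority are null.
#' Baselines are log-normal on the log2-FPKM scale (mean 5, SD 2, i.e. a
#' median around 32 FPKM with a heavy right tail); planted effects are
#' multiplicative with magnitude `effect_log2fc` on the log2 scale and one
#' sign per transcript; replicate noise is additive on the log2 scale.
#'
#' @param n_groups Number of disease groups (default 11).
#' @param n_neuronopathic Number of neuronopathic groups, the first
#'   `n_neuronopathic` in order (default 7).
#' @param replicates Biological replicates per group, including control
#'   (default 4).
#' @param n_null Transcripts with no planted effect (default 2700).
#' @param n_universal Markers altered in every disease group (default 60).
#' @param n_shared_partial Markers altered in a random subset of 2..(G-1)
#'   groups (default 90).
#' @param n_neuro_specific Markers altered in >= 5 neuronopathic groups and no
#'   others (default 60).
#' @param n_singleton Markers altered in exactly one group (default 90).
#' @param baseline_log_mean,baseline_log_sd Log2-FPKM baseline distribution
#'   (defaults 5 and 2).
#' @param effect_log2fc Planted effect magnitude, log2 scale (default 3).
#' @param noise_sd Replicate noise SD, log2 scale (default 0.3).
#' @param min_specific_groups Minimum neuronopathic groups affected by a
#'   neuro-specific marker (default 5).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @param group_labels `"synthetic"` for abstract labels G01..Gn, `"study"`
#'   for the real 11 MPS type/subtype names and flags (requires
#'   `n_groups = 11`, `n_neuronopathic = 7`).
#' @return A validated list of class `mps_sim_spec`.
#' @export
synthetic_spec <- function(n_groups = 11L, n_neuronopathic = 7L, replicates = 4L,
                           n_null = 2700L, n_universal = 60L,
                           n_shared_partial = 90L, n_neuro_specific = 60L,
                           n_singleton = 90L,
                           baseline_log_mean = 5, baseline_log_sd = 2,
                           effect_log2fc = 3, noise_sd = 0.3,
                           min_specific_groups = 5L,
                           seed = 1L,
                           group_labels = c("synthetic", "study")) {
  spec <- list(
    n_groups = as.integer(n_groups), n_neuronopathic = as.integer(n_neuronopathic),
    replicates = as.integer(replicates),
    n_null = as.integer(n_null), n_universal = as.integer(n_universal),
    n_shared_partial = as.integer(n_shared_partial),
    n_neuro_specific = as.integer(n_neuro_specific),
    n_singleton = as.integer(n_singleton),
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    effect_log2fc = effect_log2fc, noise_sd = noise_sd,
    min_specific_groups = as.integer(min_specific_groups),
    seed = as.integer(seed), group_labels = match.arg(group_labels)
  )
  counts <- c(spec$n_null, spec$n_universal, spec$n_shared_partial,
              spec$n_neuro_specific, spec$n_singleton)
  if (any(counts < 0)) abort("transcript counts must be >= 0")
  if (spec$replicates < 2) abort("replicates must be >= 2")
  if (spec$n_neuronopathic >= spec$n_groups || spec$n_neuronopathic < 1) {
    abort("n_neuronopathic must be in [1, n_groups)")
  }
  if (spec$effect_log2fc < 0 || spec$noise_sd < 0) {
    abort("effect_log2fc and noise_sd must be >= 0")
  }
  if (spec$n_neuro_specific > 0 && spec$min_specific_groups > spec$n_neuronopathic) {
    abort("min_specific_groups exceeds the number of neuronopathic groups")
  }
  if (spec$n_shared_partial > 0 && spec$n_groups < 3) {
    abort("shared_partial markers need at least 3 disease groups")
  }
  if (spec$group_labels == "study" &&
      (spec$n_groups != 11L || spec$n_neuronopathic != 7L)) {
    abort("study labels require 11 groups with 7 neuronopathic")
  }
  structure(spec, class = "mps_sim_spec")
}

#' The 11-type MPS study design
#'
#' Sample metadata for the real study layout: 11 MPS types/subtypes (I, II,
#' IIIA, IIIB, IIIC, IIID and VII neuronopathic; IVA, IVB, VI and IX
#' non-neuronopathic) plus a fibroblast control line, with a fixed number of
#' biological replicates each.
#'
#' @param replicates Replicates per group, default 4.
#' @return An `mps_design` tibble.
#' @export
mps_study_design <- function(replicates = 4L) {
  groups <- c("I", "II", "IIIA", "IIIB", "IIIC", "IIID", "VII",
              "IVA", "IVB", "VI", "IX")
  neuro <- c(rep(TRUE, 7), rep(FALSE, 4))
  make_design(groups, neuro, replicates)
}

make_design <- function(groups, neuro, replicates, control = "control") {
  all_groups <- c(control, groups)
  all_neuro <- c(NA, neuro)
  new_design(
    sample_id = unlist(lapply(all_groups, function(g) paste0(g, "_r", seq_len(replicates)))),
    group = rep(all_groups, each = replicates),
    neuronopathic = rep(all_neuro, each = replicates)
  )
}

#' Generate a synthetic FPKM study
#'
#' Draws per-transcript baselines on the log2-FPKM scale, plants the marker
#' classes of the spec (universal, shared-partial, neuro-specific, singleton),
#' and emits `2^(baseline + effect + noise)` FPKM values, so every value is
#' finite and non-negative. The planted effect has one sign and one magnitude
#' per transcript and applies to every sample of an affected disease group;
#' control samples are never affected. Deterministic given the spec's seed.
#'
#' @param spec An `mps_sim_spec`, e.g. [synthetic_spec()].
#' @return A list of class `mps_sim` with elements `expr` (wide FPKM tibble),
#'   `design` (`mps_design`), and `truth` (tibble: `transcript_id`, `class`,
#'   `sign`, `affected_groups` list column, `effect_log2fc`).
#' @export
simulate_expression <- function(spec = synthetic_spec()) {
  if (!inherits(spec, "mps_sim_spec")) spec <- do.call(synthetic_spec, spec)
  set.seed(spec$seed)

  if (spec$group_labels == "study") {
    design <- mps_study_design(spec$replicates)
  } else {
    design <- make_design(sprintf("G%02d", seq_len(spec$n_groups)),
                          seq_len(spec$n_groups) <= spec$n_neuronopathic,
                          spec$replicates)
  }
  groups <- design_groups(design)$group
  neuro_groups <- groups[seq_len(spec$n_neuronopathic)]
  G <- spec$n_groups

  classes <- rep(c("universal", "shared_partial", "neuro_specific", "singleton", "null"),
                 c(spec$n_universal, spec$n_shared_partial, spec$n_neuro_specific,
                   spec$n_singleton, spec$n_null))
  n <- length(classes)
  if (n == 0) abort("spec generates no transcripts")
  ids <- sprintf("T%05d", seq_len(n))

  pick_one <- function(values) values[sample.int(length(values), 1L)]
  affected <- lapply(seq_len(n), function(i) {
    switch(classes[i],
      universal = groups,
      shared_partial = groups[sort(sample.int(G, pick_one(2:(G - 1L))))],
      neuro_specific = {
        size <- pick_one(spec$min_specific_groups:spec$n_neuronopathic)
        neuro_groups[sort(sample.int(spec$n_neuronopathic, size))]
      },
      singleton = groups[sample.int(G, 1L)],
      character(0)
    )
  })
  signs <- ifelse(stats::runif(n) < 0.5, -1, 1)
  signs[classes == "null"] <- 0
  baselines <- rnorm(n, spec$baseline_log_mean, spec$baseline_log_sd)

  n_samples <- nrow(design)
  effect_mat <- matrix(0, n, n_samples)
  sample_group <- design$group
  for (gi in seq_along(groups)) {
    cols <- which(sample_group == groups[gi])
    hit <- vapply(affected, function(a) groups[gi] %in% a, logical(1))
    effect_mat[hit, cols] <- spec$effect_log2fc * signs[hit]
  }
  noise <- matrix(rnorm(n * n_samples, 0, spec$noise_sd), n, n_samples)
  fpkm <- 2^(baselines + effect_mat + noise)
  colnames(fpkm) <- design$sample_id

  expr <- dplyr::bind_cols(tibble::tibble(transcript_id = ids),
                           tibble::as_tibble(fpkm))
  truth <- tibble::tibble(
    transcript_id = ids, class = classes, sign = signs,
    affected_groups = affected,
    effect_log2fc = ifelse(classes == "null", 0, spec$effect_log2fc * signs)
  )
  structure(list(expr = expr, design = design, truth = truth, spec = spec),
            class = "mps_sim")
}

#' Recovery statistics against the planted truth
#'
#' Compares a selected marker list with the planted truth of one class:
#' recall is the fraction of that class recovered; false positives are
#' selected transcripts of any other class (including null).
#'
#' @param truth Truth tibble from [simulate_expression()].
#' @param selected_ids Character vector of selected transcript ids.
#' @param class Planted class the selection targets (e.g. `"universal"`,
#'   `"neuro_specific"`).
#' @return A tibble with `class`, `n_planted`, `n_recovered`, `recall`,
#'   `false_positive_count`.
#' @export
truth_confusion <- function(truth, selected_ids, class = "universal") {
  unknown <- setdiff(selected_ids, truth$transcript_id)
  if (length(unknown) > 0) {
    abort(sprintf("selected transcript '%s' is not in the truth table", unknown[1]))
  }
  planted <- truth$transcript_id[truth$class == class]
  n_rec <- length(intersect(selected_ids, planted))
  tibble::tibble(
    class = class,
    n_planted = length(planted),
    n_recovered = n_rec,
    recall = if (length(planted) == 0) NA_real_ else n_rec / length(planted),
    false_positive_count = length(setdiff(selected_ids, planted))
  )
}

#' @method tidy mps_sim
#' @export
tidy.mps_sim <- function(x, ...) x$truth

#' @method glance mps_sim
#' @export
glance.mps_sim <- function(x, ...) {
  dplyr::count(x$truth, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n") |>
    dplyr::mutate(n_transcripts = nrow(x$truth),
                  n_samples = nrow(x$design))
}
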