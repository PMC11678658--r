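# Neuronopathy-specific marker classification: partition the disease groups
# by the neuronopathic flag, select transcripts altered in at least m target
# (neuronopathic) groups and in none of the excluded (non-neuronopathic)
# groups, the target-restricted sharing spectrum, and per-group
# high-fold-change lists.

#' Partition disease groups by the neuronopathic flag
#'
#' @param design An `mps_design` tibble with at least one group of each flag.
#' @return A list of class `mps_partition` with character vectors `target`
#'   (neuronopathic) and `excluded` (non-neuronopathic), in design order.
#' @export
partition_groups <- function(design) {
  gr <- design_groups(design)
  target <- gr$group[gr$neuronopathic]
  excluded <- gr$group[!gr$neuronopathic]
  if (length(target) == 0 || length(excluded) == 0) {
    abort("partition requires at least one neuronopathic and one non-neuronopathic group")
  }
  structure(list(target = target, excluded = excluded), class = "mps_partition")
}

#' Select markers specific to the target (neuronopathic) groups
#'
#' A transcript qualifies when it is altered in at least `min_target_groups`
#' target groups and in none of the excluded groups. The exclusion is
#' absolute: a single altered call in an excluded group disqualifies the
#' transcript regardless of fold change. Direction is summarised as
#' `"up"`/`"down"` when all altered calls agree and `"mixed"` otherwise.
#'
#' @param profiles An `mps_profiles` tibble.
#' @param partition An `mps_partition` list.
#' @param min_target_groups Minimum number of altered target groups, default 5.
#' @return A tibble of class `mps_specific`: `transcript_id`,
#'   `n_target_altered`, `target_groups` (list column), `direction`; sorted by
#'   `n_target_altered` descending then transcript id.
#' @export
select_specific <- function(profiles, partition, min_target_groups = 5L) {
  if (min_target_groups < 1) abort("min_target_groups must be >= 1")
  rows <- profiles |>
    dplyr::mutate(
      target_groups = purrr::map(.data$altered_groups, intersect, partition$target),
      n_target_altered = lengths(.data$target_groups),
      n_excluded = purrr::map_int(.data$altered_groups,
                                  function(g) length(intersect(g, partition$excluded)))
    ) |>
    dplyr::filter(.data$n_target_altered >= min_target_groups, .data$n_excluded == 0L) |>
    dplyr::mutate(
      direction = purrr::map2_chr(.data$direction, .data$target_groups,
                                  function(d, g) direction_summary(d[g]))
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_target_altered), .data$transcript_id) |>
    dplyr::select("transcript_id", "n_target_altered", "target_groups", "direction")
  structure(rows, partition = partition, class = c("mps_specific", class(rows)))
}

#' Target-restricted sharing spectrum
#'
#' Sharing spectrum over the target (neuronopathic) groups only, with the
#' exclusion rule applied: a transcript contributes to `exactly_k` at the
#' number of target groups in which it is altered, but only if it is altered
#' in zero excluded groups.
#'
#' @param profiles An `mps_profiles` tibble.
#' @param partition An `mps_partition` list.
#' @return An `mps_spectrum` tibble over k = 1..number of target groups.
#' @export
specific_sharing_spectrum <- function(profiles, partition) {
  n_target <- purrr::map_int(profiles$altered_groups,
                             function(g) length(intersect(g, partition$target)))
  n_excl <- purrr::map_int(profiles$altered_groups,
                           function(g) length(intersect(g, partition$excluded)))
  eligible <- n_target[n_excl == 0L]
  G <- length(partition$target)
  ks <- seq_len(G)
  exactly <- vapply(ks, function(k) sum(eligible == k), integer(1))
  at_least <- rev(cumsum(rev(exactly)))
  structure(tibble::tibble(k = ks, exactly_k = exactly, at_least_k = at_least),
            class = c("mps_spectrum", "tbl_df", "tbl", "data.frame"))
}

#' Per-group high-fold-change lists
#'
#' For each disease group, the altered transcripts whose absolute log2 fold
#' change exceeds `fc_threshold` (strict `>`, matching the printed
#' "log2FC > 3 or < -3" rule), sorted by |log2fc| descending. Only transcripts
#' already flagged altered are considered: the significance filter precedes
#' the fold-change filter.
#'
#' @param de An `mps_de` tibble.
#' @param fc_threshold Log2 fold-change cut-off, default 3.
#' @return A tibble with columns `group`, `transcript_id`, `log2fc`,
#'   `direction`, ordered by group (design order) then |log2fc| descending.
#' @export
per_group_high_fc <- function(de, fc_threshold = 3) {
  if (fc_threshold <= 0) abort("fc_threshold must be > 0")
  groups <- de_groups(de) %||% unique(de$group)
  de |>
    dplyr::filter(.data$altered, abs(.data$log2fc) > fc_threshold) |>
    dplyr::arrange(match(.data$group, groups), dplyr::desc(abs(.data$log2fc)),
                   .data$transcript_id) |>
    dplyr::select("group", "transcript_id", "log2fc", "direction")
}
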