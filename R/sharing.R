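# Cross-type sharing: per-transcript alteration profiles, the sharing
# spectrum (how many transcripts are altered in exactly / at least k disease
# groups), and selection of fold-change-filtered markers shared across most
# groups.

#' Build per-transcript alteration profiles
#'
#' Collapses a DE call table to one row per transcript, keeping the set of
#' disease groups in which the transcript is altered together with the
#' corresponding fold changes and directions.
#'
#' @param de An `mps_de` tibble (from [call_group_de()] or
#'   [ingest_printed_table()]).
#' @return A tibble of class `mps_profiles` with columns `transcript_id`,
#'   `n_altered`, and list columns `altered_groups`, `log2fc`, `direction`
#'   (the latter two named by group, defined on the altered groups only).
#'   Transcripts altered nowhere keep empty sets. The disease-group order is
#'   carried in the `"groups"` attribute.
#' @export
build_profiles <- function(de) {
  groups <- de_groups(de) %||% unique(de$group)
  if (anyDuplicated(paste(de$transcript_id, de$group, sep = "\r"))) {
    abort("duplicate (transcript, group) rows in DE table")
  }
  prof <- de |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      n_altered = sum(.data$altered),
      altered_groups = list(.data$group[.data$altered]),
      log2fc = list(setNames(.data$log2fc[.data$altered], .data$group[.data$altered])),
      direction = list(setNames(.data$direction[.data$altered], .data$group[.data$altered])),
      .groups = "drop"
    )
  prof <- prof[match(unique(de$transcript_id), prof$transcript_id), ]
  structure(prof, groups = groups, class = c("mps_profiles", class(prof)))
}

#' Sharing spectrum over disease groups
#'
#' Counts transcripts by the number of disease groups in which they are
#' altered: `exactly_k` and the cumulative `at_least_k`, for k = 1..G.
#'
#' @param profiles An `mps_profiles` tibble.
#' @param n_groups Number of disease groups; defaults to the profile
#'   attribute.
#' @return A tibble of class `mps_spectrum` with columns `k`, `exactly_k`,
#'   `at_least_k`.
#' @export
sharing_spectrum <- function(profiles, n_groups = NULL) {
  G <- n_groups %||% length(attr(profiles, "groups"))
  ks <- seq_len(G)
  exactly <- vapply(ks, function(k) sum(profiles$n_altered == k), integer(1))
  at_least <- rev(cumsum(rev(exactly)))
  structure(tibble::tibble(k = ks, exactly_k = exactly, at_least_k = at_least),
            class = c("mps_spectrum", "tbl_df", "tbl", "data.frame"))
}

direction_summary <- function(dirs) {
  u <- unique(unname(dirs))
  if (length(u) == 1) u else "mixed"
}

#' Select markers shared across many disease groups
#'
#' A transcript is a shared marker when it is altered in at least `min_groups`
#' disease groups and its largest absolute log2 fold change over the altered
#' groups exceeds `fc_threshold` (strict `>`). With the default threshold
#' `log2(2.5)` this is the "linear fold change above 2.5 somewhere" rule. Rows
#' are ordered by number of altered groups (descending) then transcript id;
#' per-group cells carry the log2 fold change where altered and `NA` (the
#' masked token `"X"` on disk) otherwise.
#'
#' @param profiles An `mps_profiles` tibble.
#' @param min_groups Minimum number of altered groups, default 10.
#' @param fc_threshold Log2-scale fold-change cut-off, default `log2(2.5)`.
#' @return A tibble of class `mps_markers`: `transcript_id`,
#'   `n_groups_altered`, `direction_summary`, then one numeric column per
#'   disease group (masked as `NA` where not altered).
#' @export
select_shared_markers <- function(profiles, min_groups = 10L,
                                  fc_threshold = log2(2.5)) {
  groups <- attr(profiles, "groups")
  if (min_groups < 1) abort("min_groups must be >= 1")
  keep <- profiles |>
    dplyr::filter(
      .data$n_altered >= min_groups,
      purrr::map_lgl(.data$log2fc, function(fc) {
        length(fc) > 0 && max(abs(fc)) > fc_threshold
      })
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_altered), .data$transcript_id)
  cells <- purrr::map(keep$log2fc, function(fc) {
    setNames(fc[groups], groups)
  })
  grid <- if (length(cells) > 0) {
    tibble::as_tibble(do.call(rbind, cells))
  } else {
    tibble::as_tibble(matrix(numeric(0), nrow = 0, ncol = length(groups),
                             dimnames = list(NULL, groups)))
  }
  out <- dplyr::bind_cols(
    tibble::tibble(
      transcript_id = keep$transcript_id,
      n_groups_altered = keep$n_altered,
      direction_summary = purrr::map_chr(keep$direction, function(d) {
        if (length(d) == 0) "none" else direction_summary(d)
      })
    ),
    grid
  )
  structure(out, groups = groups, class = c("mps_markers", class(out)))
}

#' Marker table as a masked heatmap matrix
#'
#' @param markers An `mps_markers` tibble.
#' @param design Optional `mps_design`; its disease-group order fixes the
#'   column order (defaults to the order carried by `markers`).
#' @return A numeric matrix (transcripts x groups) of log2 fold changes with
#'   `NA` in masked (not altered) cells.
#' @export
heatmap_matrix <- function(markers, design = NULL) {
  groups <- if (!is.null(design)) design_groups(design)$group else attr(markers, "groups")
  m <- as.matrix(markers[, groups, drop = FALSE])
  rownames(m) <- markers$transcript_id
  m
}

#' @method glance mps_spectrum
#' @export
glance.mps_spectrum <- function(x, ...) {
  tibble::tibble(
    n_groups = max(x$k),
    n_altered_anywhere = x$at_least_k[1],
    max_k_observed = if (any(x$exactly_k > 0)) max(x$k[x$exactly_k > 0]) else 0L
  )
}
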