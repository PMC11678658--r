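# Pipeline orchestration: run the DE -> sharing -> specificity stages end to
# end over files, and ingest printed marker tables (log2FC value or the mask
# token "X" per cell) as DE call tables.

#' Ingest a printed marker table as a DE call table
#'
#' Reads a TSV whose first column holds transcript ids and whose remaining
#' columns are disease groups, each cell holding either a log2 fold change
#' (the transcript is altered in that group) or the mask token `"X"` (not
#' altered). This is the dialect in which published marker tables are
#' reproduced, so they can be fed to the sharing and specificity stages
#' directly. p-value and q-value fields are absent-marked (`NA`).
#'
#' @param path Path to a TSV file.
#' @return An `mps_de` tibble with `altered = (cell != "X")` and `log2fc`
#'   taken from the numeric cells.
#' @export
ingest_printed_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("printed table must have transcript ids plus group columns")
  names(raw)[1] <- "transcript_id"
  groups <- setdiff(names(raw), "transcript_id")
  long <- tidyr::pivot_longer(raw, -"transcript_id",
                              names_to = "group", values_to = "cell")
  num <- suppressWarnings(as.numeric(long$cell))
  bad <- which(is.na(num) & long$cell != MASK_TOKEN)
  if (length(bad) > 0) {
    abort(sprintf("cell '%s' (transcript '%s', group '%s') is neither numeric nor '%s'",
                  long$cell[bad[1]], long$transcript_id[bad[1]], long$group[bad[1]],
                  MASK_TOKEN))
  }
  de <- tibble::tibble(
    transcript_id = long$transcript_id,
    group = long$group,
    log2fc = num,
    anova_f = NA_real_, anova_p = NA_real_,
    t_stat = NA_real_, t_p_raw = NA_real_, t_p_bonf = NA_real_,
    fdr_q = NA_real_,
    altered = long$cell != MASK_TOKEN,
    direction = dplyr::case_when(
      long$cell == MASK_TOKEN ~ "none",
      num > 0 ~ "up",
      num < 0 ~ "down",
      .default = "none"
    )
  )
  new_de_table(de, groups)
}

#' Read a long-format DE call table
#'
#' Reads back the `de.tsv` written by [run_pipeline()] or [write_table()]
#' applied to a [call_group_de()] result: one row per (transcript, group),
#' with `altered` encoded 0/1 and masked numeric cells as `"X"`.
#'
#' @param path Path to a TSV file.
#' @return An `mps_de` tibble.
#' @export
read_de_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = MASK_TOKEN)
  need <- c("transcript_id", "group", "log2fc", "altered", "direction")
  if (!all(need %in% names(raw))) {
    abort(sprintf("DE table must have columns: %s", paste(need, collapse = ", ")))
  }
  num_cols <- intersect(c("log2fc", "anova_f", "anova_p", "t_stat",
                          "t_p_raw", "t_p_bonf", "fdr_q"), names(raw))
  raw <- parse_numeric_columns_allow_na(raw, num_cols)
  raw$altered <- raw$altered %in% c("1", "TRUE", "true")
  new_de_table(raw, unique(raw$group))
}

parse_numeric_columns_allow_na <- function(tbl, cols) {
  for (cn in cols) {
    v <- tbl[[cn]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value '%s' in column '%s', row %d", v[bad[1]], cn, bad[1]))
    }
    tbl[[cn]] <- num
  }
  tbl
}

#' Read a marker membership table as alteration profiles
#'
#' Reads a TSV with columns `transcript_id`, `direction` (`up`/`down`) and
#' `groups` (comma-joined group labels), the dialect in which published
#' specific-marker tables list the types where each transcript is altered.
#'
#' @param path Path to a TSV file.
#' @param groups Full ordered vector of disease-group labels the profiles
#'   live over (alterations outside `groups` are rejected).
#' @return An `mps_profiles` tibble; fold changes are absent-marked (`NA`).
#' @export
read_marker_membership <- function(path, groups) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("transcript_id", "direction", "groups")
  if (!all(need %in% names(raw))) {
    abort(sprintf("membership table must have columns: %s", paste(need, collapse = ", ")))
  }
  sets <- purrr::map(stringr::str_split(raw$groups, ","), stringr::str_trim)
  unknown <- setdiff(unlist(sets), groups)
  if (length(unknown) > 0) abort(sprintf("unknown group label '%s'", unknown[1]))
  prof <- tibble::tibble(
    transcript_id = raw$transcript_id,
    n_altered = lengths(sets),
    altered_groups = sets,
    log2fc = purrr::map(sets, function(g) setNames(rep(NA_real_, length(g)), g)),
    direction = purrr::map2(raw$direction, sets,
                            function(d, g) setNames(rep(d, length(g)), g))
  )
  structure(prof, groups = groups, class = c("mps_profiles", class(prof)))
}

#' Run the full marker analysis over files
#'
#' Orchestrates every stage: reads the FPKM matrix, design and optional
#' configuration; calls per-group differential expression; builds profiles,
#' the sharing spectrum, the shared-marker table and its heatmap export; and,
#' when the design carries both neuronopathic and non-neuronopathic groups,
#' the neuronopathy-specific markers, the target-restricted spectrum and the
#' per-group high-fold-change lists. All outputs are deterministic TSVs under
#' `out_dir`, plus a JSON run manifest with input digests.
#'
#' @param matrix_path FPKM matrix TSV.
#' @param design_path Sample metadata TSV.
#' @param config An `mps_config`, a path to a YAML/JSON configuration, or
#'   `NULL` for defaults.
#' @param out_dir Output directory, created if needed.
#' @return The manifest, invisibly: a list with the configuration snapshot,
#'   input digests, output file list and timestamps.
#' @export
run_pipeline <- function(matrix_path, design_path, config = NULL, out_dir = ".") {
  cfg <- if (is.null(config)) {
    analysis_config()
  } else if (inherits(config, "mps_config")) {
    config
  } else {
    read_analysis_config(config)
  }
  expr <- read_expression_matrix(matrix_path)
  design <- read_design(design_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  outputs <- character(0)
  emit <- function(tbl, name) {
    path <- file.path(out_dir, name)
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    write_table(tbl, path)
    outputs <<- c(outputs, name)
  }

  de <- call_group_de(expr, design, cfg)
  emit(tidy(de), "de.tsv")

  profiles <- build_profiles(de)
  emit(sharing_spectrum(profiles), "spectrum.tsv")

  markers <- select_shared_markers(profiles, cfg$shared_min_groups, cfg$shared_fc_threshold)
  emit(markers, "shared_markers.tsv")
  hm <- heatmap_matrix(markers, design)
  emit(dplyr::bind_cols(tibble::tibble(transcript_id = rownames(hm)),
                        tibble::as_tibble(hm)),
       "heatmap.tsv")

  gr <- design_groups(design)
  if (any(gr$neuronopathic) && any(!gr$neuronopathic)) {
    part <- partition_groups(design)
    emit(select_specific(profiles, part, cfg$specific_min_groups), "neuro_specific.tsv")
    emit(specific_sharing_spectrum(profiles, part), "neuro_spectrum.tsv")
    high <- per_group_high_fc(de, cfg$high_fc_threshold)
    for (g in gr$group) {
      emit(high[high$group == g, c("transcript_id", "log2fc", "direction")],
           file.path("high_fc", paste0(g, ".tsv")))
    }
  }

  manifest <- list(
    config = unclass(cfg),
    inputs = list(
      matrix = list(path = matrix_path, md5 = unname(tools::md5sum(matrix_path))),
      design = list(path = design_path, md5 = unname(tools::md5sum(design_path)))
    ),
    outputs = lapply(setNames(outputs, outputs), function(f) {
      unname(tools::md5sum(file.path(out_dir, f)))
    }),
    seed = cfg$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
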