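# Reading, validation and writing of the pipeline's tabular interfaces.
# All on-disk formats are TSV (UTF-8, "." decimal); masked numeric cells are
# written as the literal token "X"; numbers are fixed to 6 significant digits
# so regenerated files are byte-identical.

MASK_TOKEN <- "X"

format_num <- function(x, digits = 6) {
  ifelse(is.na(x), MASK_TOKEN, sprintf("%.*g", digits, x))
}

#' Read a transcript-by-sample FPKM matrix
#'
#' Reads a tab-separated expression matrix whose first column holds transcript
#' identifiers and whose header row holds sample identifiers. Values are FPKM
#' (fragments per kilobase per million mapped reads) and must be finite and
#' non-negative.
#'
#' @param path Path to a TSV file.
#' @return A tibble with a `transcript_id` character column followed by one
#'   numeric column per sample, ordered as in the file.
#' @export
read_expression_matrix <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) {
    abort("expression matrix must have a transcript id column and at least one sample column")
  }
  names(raw)[1] <- "transcript_id"
  validate_expression_tbl(parse_numeric_columns(raw, setdiff(names(raw), "transcript_id")))
}

parse_numeric_columns <- function(tbl, cols) {
  for (cn in cols) {
    v <- tbl[[cn]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value '%s' in column '%s', row %d",
                    v[bad[1]], cn, bad[1]))
    }
    if (anyNA(v)) {
      abort(sprintf("missing value in column '%s'", cn))
    }
    tbl[[cn]] <- num
  }
  tbl
}

validate_expression_tbl <- function(tbl) {
  ids <- tbl$transcript_id
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate transcript id '%s'", ids[duplicated(ids)][1]))
  }
  samples <- setdiff(names(tbl), "transcript_id")
  if (anyDuplicated(samples)) {
    abort(sprintf("duplicate sample id '%s'", samples[duplicated(samples)][1]))
  }
  for (cn in samples) {
    v <- tbl[[cn]]
    if (!is.numeric(v)) abort(sprintf("column '%s' is not numeric", cn))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad) > 0) {
      abort(sprintf("negative or non-finite FPKM in column '%s', row %d (transcript '%s')",
                    cn, bad[1], ids[bad[1]]))
    }
  }
  tibble::as_tibble(tbl)
}

#' Write an FPKM matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; numeric cells are written with 6
#' significant digits.
#'
#' @param tbl A tibble as returned by [read_expression_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(tbl, path) {
  out <- tbl
  for (cn in setdiff(names(out), "transcript_id")) out[[cn]] <- format_num(out[[cn]])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' The design TSV has columns `sample_id`, `group` and `neuronopathic`, the
#' last holding `yes` / `no` for disease groups and `control` for control
#' samples. The study design proper is one control line plus eleven MPS
#' types/subtypes, seven of them neuronopathic.
#'
#' @param path Path to a TSV file.
#' @return A design tibble of class `mps_design` with columns `sample_id`,
#'   `group`, `is_control` and `neuronopathic` (logical, `NA` for control
#'   samples); the control group label is stored in the `"control"` attribute.
#' @export
read_design <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("sample_id", "group", "neuronopathic")
  if (!all(need %in% names(raw))) {
    abort(sprintf("design file must have columns: %s", paste(need, collapse = ", ")))
  }
  flag <- tolower(raw$neuronopathic)
  if (!all(flag %in% c("yes", "no", "control"))) {
    abort("column 'neuronopathic' must be one of yes/no/control")
  }
  new_design(raw$sample_id, raw$group, dplyr::case_when(
    flag == "yes" ~ TRUE, flag == "no" ~ FALSE, .default = NA
  ))
}

new_design <- function(sample_id, group, neuronopathic) {
  tbl <- tibble::tibble(
    sample_id = as.character(sample_id),
    group = as.character(group),
    is_control = is.na(neuronopathic),
    neuronopathic = neuronopathic
  )
  validate_design(tbl)
}

validate_design <- function(tbl) {
  if (anyDuplicated(tbl$sample_id)) {
    abort(sprintf("sample '%s' assigned more than once",
                  tbl$sample_id[duplicated(tbl$sample_id)][1]))
  }
  if (!any(tbl$is_control)) abort("design has no control samples")
  ctrl <- unique(tbl$group[tbl$is_control])
  if (length(ctrl) > 1) abort("control samples span more than one group label")
  if (ctrl %in% tbl$group[!tbl$is_control]) {
    abort(sprintf("control label '%s' is also used as a disease group", ctrl))
  }
  flag_per_group <- dplyr::distinct(tbl[!tbl$is_control, c("group", "neuronopathic")])
  if (anyDuplicated(flag_per_group$group)) {
    abort("inconsistent neuronopathic flag within a group")
  }
  counts <- table(tbl$group)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    abort(sprintf("group '%s' has fewer than 2 samples", small[1]))
  }
  structure(tbl, control = ctrl, class = c("mps_design", class(tbl)))
}

#' Control group label of a design
#' @param design An `mps_design` tibble.
#' @return The control label, a length-one character vector.
#' @export
control_label <- function(design) attr(design, "control")

#' Disease groups of a design
#'
#' @param design An `mps_design` tibble.
#' @return A tibble with one row per disease group, columns `group` and
#'   `neuronopathic`, in order of first appearance.
#' @export
design_groups <- function(design) {
  dplyr::distinct(tibble::as_tibble(design)[!design$is_control, c("group", "neuronopathic")])
}

#' Write a design tibble to TSV
#' @param design An `mps_design` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  out <- tibble::tibble(
    sample_id = design$sample_id,
    group = design$group,
    neuronopathic = dplyr::case_when(
      design$is_control ~ "control",
      design$neuronopathic ~ "yes",
      .default = "no"
    )
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Analysis configuration
#'
#' Bundles the thresholds of the analysis. Defaults mirror the study's printed
#' cut-offs: the dual significance rule FDR < 0.1 and p < 0.1, shared markers
#' altered in at least 10 of 11 types with linear fold change above 2.5
#' (|log2FC| > log2 2.5), neuronopathy-specific markers altered in at least 5
#' of the 7 neuronopathic types, and the per-type high-fold-change listing at
#' |log2FC| > 3.
#'
#' @param fdr_threshold Benjamini-Hochberg FDR cut-off (strict `<`), in (0,1).
#' @param p_threshold Post hoc p cut-off (strict `<`), in (0,1); applied to the
#'   Bonferroni-adjusted p by default (see `p_on`).
#' @param shared_min_groups Minimum number of altered disease groups for a
#'   shared marker.
#' @param shared_fc_threshold Fold-change cut-off (log2 scale, strict `>`) for
#'   shared-marker selection; default `log2(2.5)`.
#' @param specific_min_groups Minimum number of altered target (neuronopathic)
#'   groups for a specific marker.
#' @param high_fc_threshold Log2 fold-change cut-off (strict `>`) for the
#'   per-group high-fold-change lists.
#' @param pseudocount Pseudocount added to mean FPKM in the fold-change ratio.
#' @param fdr_on Which p-value enters the BH adjustment across transcripts:
#'   `"anova"` (default; the omnibus ANOVA p) or `"posthoc"` (the raw post hoc
#'   p, adjusted per group).
#' @param p_on Which post hoc p the `p_threshold` applies to: `"bonferroni"`
#'   (default) or `"raw"`.
#' @param var_equal Use the pooled-variance Student t-test (default `TRUE`);
#'   `FALSE` selects Welch.
#' @param seed Integer seed recorded with the configuration.
#' @return A list of class `mps_config`.
#' @export
analysis_config <- function(fdr_threshold = 0.1,
                            p_threshold = 0.1,
                            shared_min_groups = 10L,
                            shared_fc_threshold = log2(2.5),
                            specific_min_groups = 5L,
                            high_fc_threshold = 3.0,
                            pseudocount = 1.0,
                            fdr_on = c("anova", "posthoc"),
                            p_on = c("bonferroni", "raw"),
                            var_equal = TRUE,
                            seed = 1L) {
  cfg <- list(
    fdr_threshold = fdr_threshold, p_threshold = p_threshold,
    shared_min_groups = as.integer(shared_min_groups),
    shared_fc_threshold = shared_fc_threshold,
    specific_min_groups = as.integer(specific_min_groups),
    high_fc_threshold = high_fc_threshold,
    pseudocount = pseudocount,
    fdr_on = match.arg(fdr_on), p_on = match.arg(p_on),
    var_equal = isTRUE(var_equal), seed = as.integer(seed)
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot_config(cfg$fdr_threshold > 0 && cfg$fdr_threshold < 1, "fdr_threshold must be in (0,1)")
  stopifnot_config(cfg$p_threshold > 0 && cfg$p_threshold < 1, "p_threshold must be in (0,1)")
  stopifnot_config(cfg$shared_min_groups >= 1L, "shared_min_groups must be >= 1")
  stopifnot_config(cfg$shared_fc_threshold > 0, "shared_fc_threshold must be > 0")
  stopifnot_config(cfg$specific_min_groups >= 1L, "specific_min_groups must be >= 1")
  stopifnot_config(cfg$high_fc_threshold > 0, "high_fc_threshold must be > 0")
  stopifnot_config(cfg$pseudocount > 0, "pseudocount must be > 0")
  structure(cfg, class = "mps_config")
}

stopifnot_config <- function(ok, msg) if (!isTRUE(ok)) abort(paste0("invalid configuration: ", msg))

#' Read an analysis configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys take the [analysis_config()]
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `mps_config` list.
#' @export
read_analysis_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration key '%s'", unknown[1]))
  }
  do.call(analysis_config, vals)
}

#' Write a result table to TSV
#'
#' Generic writer for the pipeline's result tibbles: numeric cells are fixed
#' to 6 significant digits, `NA` numeric cells (masked entries) are written as
#' the literal token `"X"`, list columns are comma-joined, and row order is
#' preserved, so re-running a pipeline yields byte-identical files.
#'
#' @param tbl A data frame of result records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(tbl, path) {
  out <- tibble::as_tibble(tbl)
  for (cn in names(out)) {
    v <- out[[cn]]
    if (is.list(v)) {
      out[[cn]] <- purrr::map_chr(v, function(el) paste(el, collapse = ","))
    } else if (is.numeric(v)) {
      out[[cn]] <- format_num(v)
    } else if (is.logical(v)) {
      out[[cn]] <- as.integer(v)
    }
  }
  readr::write_tsv(out, path, progress = FALSE, na = MASK_TOKEN)
  invisible(path)
}
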