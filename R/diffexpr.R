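# Differential-expression calling per disease group versus the common
# control: log2(1 + x) transform, omnibus one-way ANOVA, post hoc Student
# t-tests with Bonferroni correction, BH FDR across transcripts, and the dual
# "altered" rule (FDR < fdr_threshold AND p < p_threshold, both strict).

#' Log-transform FPKM values
#'
#' The analysis scale of the pipeline: `log2(1 + x)`. Monotone, zero at zero,
#' defined for every non-negative FPKM.
#'
#' @param x Non-negative numeric vector (FPKM).
#' @return `log2(1 + x)`.
#' @export
log2p1 <- function(x) {
  if (any(x < 0, na.rm = TRUE)) abort("log2p1() requires non-negative values")
  log2(1 + x)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA from the textbook sums of squares.
#' When every value is identical across all groups both sums of squares are
#' zero, the F statistic is undefined, and the result is flagged degenerate
#' with p = 1 (downstream such transcripts are never called altered).
#'
#' @param groups A list of two or more numeric vectors, each of length >= 2.
#' @return A list with `statistic` (F), `df` (numerator, denominator),
#'   `p.value`, and `degenerate`.
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) abort("anova_oneway() needs >= 2 groups")
  if (any(lengths(groups) < 2)) abort("every group needs >= 2 values")
  n <- lengths(groups)
  N <- sum(n)
  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(seq_along(groups), function(i) sum((groups[[i]] - means[i])^2), numeric(1)))
  df <- c(k - 1L, N - k)
  if (ssw == 0 && ssb == 0) {
    return(list(statistic = 0, df = df, p.value = 1, degenerate = TRUE))
  }
  f <- (ssb / df[1]) / (ssw / df[2])
  list(statistic = f, df = df, p.value = pf(f, df[1], df[2], lower.tail = FALSE),
       degenerate = FALSE)
}

#' Post hoc t-test of one group against control
#'
#' Two-sided Student (pooled-variance) t-test of a disease group against the
#' control, with Bonferroni correction for the number of group-versus-control
#' comparisons: `p_bonf = min(1, p_raw * n_comparisons)`. Zero pooled variance
#' is flagged degenerate: p = 1 when the means also agree, p = 0 otherwise
#' (perfect separation with no within-group spread); degenerate results are
#' never called altered downstream.
#'
#' @param group_values Numeric vector, length >= 2.
#' @param control_values Numeric vector, length >= 2.
#' @param n_comparisons Bonferroni factor, >= 1 (11 in the full study design).
#' @param var_equal Pooled-variance Student test if `TRUE` (default), Welch
#'   otherwise.
#' @return A list with `statistic` (t), `df`, `p.value` (raw),
#'   `p.bonferroni`, and `degenerate`.
#' @export
posthoc_t_vs_control <- function(group_values, control_values, n_comparisons = 1L,
                                 var_equal = TRUE) {
  if (length(group_values) < 2 || length(control_values) < 2) {
    abort("both groups need >= 2 values")
  }
  if (n_comparisons < 1) abort("n_comparisons must be >= 1")
  n1 <- length(group_values); n2 <- length(control_values)
  m1 <- mean(group_values); m2 <- mean(control_values)
  v1 <- sum((group_values - m1)^2) / (n1 - 1)
  v2 <- sum((control_values - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se == 0) {
    p <- if (m1 == m2) 1 else 0
    t <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    return(list(statistic = t, df = df, p.value = p,
                p.bonferroni = min(1, p * n_comparisons), degenerate = TRUE))
  }
  t <- (m1 - m2) / se
  p <- 2 * pt(-abs(t), df)
  list(statistic = t, df = df, p.value = p,
       p.bonferroni = min(1, p * n_comparisons), degenerate = FALSE)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH adjustment: on the sorted p-values,
#' `q(i) = min over j >= i of p(j) * n / j`, capped at 1 and mapped back to the
#' input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) abort("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Log2 fold change between group and control mean FPKM
#'
#' `log2((mean(group) + pseudocount) / (mean(control) + pseudocount))`. The
#' pseudocount keeps the ratio defined at zero expression and shrinks fold
#' changes of barely expressed transcripts toward zero.
#'
#' @param group_values Non-negative numeric vector (FPKM).
#' @param control_values Non-negative numeric vector (FPKM).
#' @param pseudocount Positive pseudocount, default 1.
#' @return A single log2 fold-change value.
#' @export
log2_fold_change <- function(group_values, control_values, pseudocount = 1) {
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  if (any(group_values < 0) || any(control_values < 0)) abort("FPKM values must be >= 0")
  log2((mean(group_values) + pseudocount) / (mean(control_values) + pseudocount))
}

# Row-wise sufficient statistics for a sample-index subset.
row_group_stats <- function(L, idx) {
  m <- rowMeans(L[, idx, drop = FALSE])
  ss <- rowSums((L[, idx, drop = FALSE] - m)^2)
  list(mean = m, ss = ss, n = length(idx))
}

#' Call per-group differential expression
#'
#' Runs the full per-transcript testing procedure: transcripts with zero FPKM
#' in every sample are dropped; values are transformed to `log2(1 + x)`; an
#' omnibus one-way ANOVA is run across the control and all disease groups;
#' each disease group is tested against control with a post hoc Student
#' t-test, Bonferroni-corrected by the number of disease groups; BH FDR is
#' computed across transcripts (on the omnibus ANOVA p by default); a
#' transcript is called altered in a group iff `fdr_q < fdr_threshold` and the
#' post hoc p (Bonferroni-adjusted by default) is `< p_threshold`. Degenerate
#' statistics (zero variance) are propagated as "not altered", never as
#' errors. Fold changes are on mean FPKM with a pseudocount.
#'
#' @param expr Expression tibble as from [read_expression_matrix()].
#' @param design An `mps_design` tibble covering every sample column.
#' @param config An `mps_config` list; defaults to [analysis_config()].
#' @return A tibble of class `mps_de` with one row per (transcript, disease
#'   group): `transcript_id`, `group`, `log2fc`, `anova_f`, `anova_p`,
#'   `t_stat`, `t_p_raw`, `t_p_bonf`, `fdr_q`, `altered`, `direction`
#'   (`"up"`/`"down"`/`"none"`). The design's disease-group order is stored in
#'   the `"groups"` attribute and the configuration in `"config"`.
#' @export
call_group_de <- function(expr, design, config = analysis_config()) {
  samples <- setdiff(names(expr), "transcript_id")
  missing <- setdiff(samples, design$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("sample '%s' is not assigned in the design", missing[1]))
  }
  X <- as.matrix(expr[, samples, drop = FALSE])
  rownames(X) <- expr$transcript_id

  keep <- rowSums(X) > 0
  X <- X[keep, , drop = FALSE]
  if (nrow(X) == 0) abort("no transcript has nonzero expression")

  groups <- design_groups(design)$group
  ctrl_idx <- which(samples %in% design$sample_id[design$is_control])
  grp_idx <- lapply(groups, function(g) {
    which(samples %in% design$sample_id[!design$is_control & design$group == g])
  })
  L <- log2p1(X)

  ctrl <- row_group_stats(L, ctrl_idx)
  stats <- lapply(grp_idx, function(idx) row_group_stats(L, idx))

  # omnibus ANOVA over control + all disease groups
  all_stats <- c(list(ctrl), stats)
  ns <- vapply(all_stats, `[[`, numeric(1), "n")
  N <- sum(ns); k <- length(all_stats)
  means_mat <- do.call(cbind, lapply(all_stats, `[[`, "mean"))
  grand <- as.vector(means_mat %*% ns) / N
  ssb <- as.vector((sweep(means_mat, 1, grand)^2) %*% ns)
  ssw <- rowSums(do.call(cbind, lapply(all_stats, `[[`, "ss")))
  df1 <- k - 1L; df2 <- N - k
  anova_degen <- ssw == 0 & ssb == 0
  f <- ifelse(anova_degen, 0, (ssb / df1) / (ssw / df2))
  anova_p <- ifelse(anova_degen, 1, pf(f, df1, df2, lower.tail = FALSE))

  G <- length(groups)
  per_group <- purrr::map2(stats, seq_along(groups), function(st, gi) {
    n1 <- st$n; n2 <- ctrl$n
    if (config$var_equal) {
      sp2 <- (st$ss + ctrl$ss) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- n1 + n2 - 2
    } else {
      v1 <- st$ss / (n1 - 1); v2 <- ctrl$ss / (n2 - 1)
      se <- sqrt(v1 / n1 + v2 / n2)
      df <- (v1 / n1 + v2 / n2)^2 /
        ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    }
    delta <- st$mean - ctrl$mean
    degen <- se == 0
    t <- ifelse(degen, ifelse(delta == 0, 0, sign(delta) * Inf), delta / se)
    p <- ifelse(degen, ifelse(delta == 0, 1, 0), 2 * pt(-abs(t), df))
    fc <- log2((rowMeans(X[, grp_idx[[gi]], drop = FALSE]) + config$pseudocount) /
                 (rowMeans(X[, ctrl_idx, drop = FALSE]) + config$pseudocount))
    tibble::tibble(
      transcript_id = rownames(X), group = groups[gi],
      log2fc = unname(fc), anova_f = unname(f), anova_p = unname(anova_p),
      t_stat = unname(t), t_p_raw = unname(p),
      t_p_bonf = pmin(1, unname(p) * G),
      degenerate = unname(degen | anova_degen),
      delta_log = unname(delta)
    )
  })
  de <- dplyr::bind_rows(per_group)

  if (config$fdr_on == "anova") {
    q_by_transcript <- setNames(bh_fdr(anova_p), rownames(X))
    de$fdr_q <- unname(q_by_transcript[de$transcript_id])
  } else {
    de <- de |>
      dplyr::group_by(.data$group) |>
      dplyr::mutate(fdr_q = bh_fdr(.data$t_p_raw)) |>
      dplyr::ungroup()
  }

  p_used <- if (config$p_on == "bonferroni") de$t_p_bonf else de$t_p_raw
  de$altered <- !de$degenerate &
    de$fdr_q < config$fdr_threshold &
    p_used < config$p_threshold
  de$direction <- dplyr::case_when(
    !de$altered ~ "none",
    de$log2fc > 0 ~ "up",
    de$log2fc < 0 ~ "down",
    .default = ifelse(de$delta_log > 0, "up", "down")
  )
  de <- de[order(match(de$transcript_id, rownames(X)), match(de$group, groups)),
           c("transcript_id", "group", "log2fc", "anova_f", "anova_p",
             "t_stat", "t_p_raw", "t_p_bonf", "fdr_q", "altered", "direction")]
  new_de_table(de, groups, config)
}

new_de_table <- function(tbl, groups, config = NULL) {
  structure(tibble::as_tibble(tbl), groups = groups, config = config,
            class = c("mps_de", class(tibble::as_tibble(tbl))))
}

#' Disease-group order carried by a DE call table
#' @param de An `mps_de` tibble.
#' @return Character vector of group labels.
#' @export
de_groups <- function(de) attr(de, "groups")

#' @method glance mps_de
#' @export
glance.mps_de <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    n_transcripts = dplyr::n_distinct(x$transcript_id),
    n_groups = length(de_groups(x)),
    n_altered_calls = sum(x$altered),
    n_altered_transcripts = dplyr::n_distinct(x$transcript_id[x$altered]),
    fdr_threshold = cfg$fdr_threshold %||% NA_real_,
    p_threshold = cfg$p_threshold %||% NA_real_
  )
}

#' @method tidy mps_de
#' @export
tidy.mps_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mps_de")
  attr(out, "groups") <- NULL
  attr(out, "config") <- NULL
  out
}
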