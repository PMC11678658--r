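# Shared fixtures and independent oracles for the suite.

shared_fixture <- function() {
  system.file("extdata", "mps_shared_markers_log2fc.tsv", package = "mpsmarkers")
}

membership_fixture <- function() {
  system.file("extdata", "mps_neuro_markers_membership.tsv", package = "mpsmarkers")
}

mps_group_names <- c("I", "II", "IIIA", "IIIB", "IIIC", "IIID", "VII",
                     "IVA", "IVB", "VI", "IX")

# Brute-force step-up BH, written from the definition and independent of
# p.adjust: q_i = min over candidate thresholds t >= p_i of t * n / #{p <= t},
# capped at 1. Tie-safe because #{p <= t} takes the largest rank of a tie run.
bh_brute <- function(p) {
  n <- length(p)
  vapply(p, function(pi) {
    cand <- p[p >= pi]
    min(1, min(vapply(cand, function(t) t * n / sum(p <= t), numeric(1))))
  }, numeric(1))
}

# All permutations of a vector (n! rows), for exhaustive order checks.
all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

# A tiny two-group-plus-control study for unit tests.
toy_design <- function(groups = c("A", "B"), neuro = c(TRUE, FALSE), replicates = 3) {
  tbl <- tibble::tibble(
    sample_id = c(paste0("ctrl_", seq_len(replicates)),
                  unlist(lapply(groups, function(g) paste0(g, "_", seq_len(replicates))))),
    group = c(rep("control", replicates), rep(groups, each = replicates)),
    neuronopathic = c(rep("control", replicates),
                      rep(ifelse(neuro, "yes", "no"), each = replicates))
  )
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, path)
  on.exit(unlink(path))
  read_design(path)
}

# Hand-built profiles for selection-rule tests.
manual_profiles <- function(rows, groups) {
  prof <- tibble::tibble(
    transcript_id = names(rows),
    n_altered = lengths(rows),
    altered_groups = unname(rows),
    log2fc = purrr::map(unname(rows), function(g) setNames(rep(2, length(g)), g)),
    direction = purrr::map(unname(rows), function(g) setNames(rep("up", length(g)), g))
  )
  structure(prof, groups = groups, class = c("mps_profiles", class(prof)))
}
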