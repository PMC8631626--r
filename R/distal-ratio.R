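#' Length-normalized distal ratio of a coverage track
#'
#' The core APA statistic: with `D` and `P` the summed depths over the distal
#' and proximal segments and `Ld`, `Lp` their lengths,
#' `ratio = (D/Ld) / (D/Ld + P/Lp)`. The ratio lies in `[0, 1]`, is invariant
#' to multiplying all depths by a positive constant, and is missing (`NA`)
#' when both segments have zero depth — such samples are excluded listwise
#' from downstream comparisons, mirroring the exclusion of sequencing runs
#' with no long-3'UTR coverage.
#'
#' @param cov [coverage_track()] spanning both segments of `spec`.
#' @param spec [region_spec()]; defaults to the SERPINA1 regions.
#' @param sample_id Optional sample label carried through.
#' @return A `sample_ratio` list: `sample_id`, `ratio`,
#'   `proximal_mean_depth`, `distal_mean_depth`.
#' @examples
#' spec <- serpina1_region_spec()
#' cov <- simulate_coverage(isoform_model(S = 1, L = 1, spec = spec,
#'                                        mean_depth = 100), seed = 1)
#' compute_distal_ratio(cov, spec)$ratio # near 1/3
#' @export
compute_distal_ratio <- function(cov, spec = serpina1_region_spec(),
                                 sample_id = NA_character_) {
  stopifnot(inherits(cov, "coverage_track"), inherits(spec, "region_spec"))
  p_depth <- track_slice(cov, spec$proximal)
  d_depth <- track_slice(cov, spec$distal)
  p_mean <- sum(p_depth) / length(p_depth)
  d_mean <- sum(d_depth) / length(d_depth)
  ratio <- if (p_mean + d_mean == 0) NA_real_ else d_mean / (d_mean + p_mean)
  structure(list(sample_id = sample_id, ratio = ratio,
                 proximal_mean_depth = p_mean, distal_mean_depth = d_mean),
            class = "sample_ratio")
}

#' @export
print.sample_ratio <- function(x, ...) {
  cat(sprintf("<sample_ratio> %s: ratio = %s (proximal %.2f, distal %.2f reads/base)\n",
              ifelse(is.na(x$sample_id), "(unnamed)", x$sample_id),
              ifelse(is.na(x$ratio), "NA", sprintf("%.4f", x$ratio)),
              x$proximal_mean_depth, x$distal_mean_depth))
  invisible(x)
}

# Mann-Whitney U, exact for small untied samples, normal approximation with
# tie correction otherwise.
rank_test_p <- function(a, b, exact_max_n = 8) {
  exact <- length(a) <= exact_max_n && length(b) <= exact_max_n &&
    !anyDuplicated(c(a, b))
  stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
}

#' Compare distal ratios between two cohorts
#'
#' Fold change of group medians (case over control) with a two-sided
#' Mann-Whitney U p-value (exact when both groups have at most 8 untied
#' observations, normal approximation with tie correction otherwise).
#' Missing ratios are dropped before testing.
#'
#' @param ratios_case,ratios_control Numeric vectors of ratios (may contain
#'   `NA`).
#' @return A `cohort_comparison` list: `fold_change`, `p_value`, `n_case`,
#'   `n_control`, `median_case`, `median_control`, and — when the control
#'   median is zero and the fold is undefined — `median_difference`.
#' @examples
#' compare_cohorts(c(0.05, 0.06, 0.08), c(0.02, 0.03, 0.04)) # fold 2, p 0.1
#' @export
compare_cohorts <- function(ratios_case, ratios_control) {
  a <- ratios_case[!is.na(ratios_case)]
  b <- ratios_control[!is.na(ratios_control)]
  if (length(a) == 0 || length(b) == 0)
    stop("a group is empty after dropping missing ratios")
  med_a <- stats::median(a); med_b <- stats::median(b)
  fold <- if (med_b == 0) NA_real_ else med_a / med_b
  structure(list(
    fold_change = fold,
    median_difference = if (med_b == 0) med_a - med_b else NA_real_,
    p_value = rank_test_p(a, b),
    n_case = length(a), n_control = length(b),
    median_case = med_a, median_control = med_b
  ), class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  est <- if (is.na(x$fold_change))
    sprintf("median difference %.4f (control median 0)", x$median_difference)
  else sprintf("fold change %.3f", x$fold_change)
  cat(sprintf("<cohort_comparison> %s, p = %.3g (n = %d vs %d)\n",
              est, x$p_value, x$n_case, x$n_control))
  invisible(x)
}

#' Stratified cohort comparisons of the distal ratio
#'
#' Runs one case-vs-control [compare_cohorts()] per stratum (e.g. per PI
#' genotype), plus pairwise within-case rank tests of each non-reference
#' stratum against the reference stratum. Strata with fewer than 2 samples
#' in either arm are flagged low-power but still reported. Stratum values
#' outside `known_levels` (when given) are grouped under `"other"` with a
#' warning.
#'
#' @param ratios Data frame with columns `sample_id` and `ratio`.
#' @param table Sample table with columns `sample_id`, `group`
#'   (`"case"`/`"control"`), and the stratum column.
#' @param stratum_key Name of the stratum column in `table` (e.g.
#'   `"genotype"`).
#' @param reference Reference stratum for within-case tests; defaults to
#'   `"MM"` when present, otherwise the first stratum.
#' @param known_levels Optional allowed stratum values.
#' @return List with tibbles `per_stratum` (stratum, n_case, n_control,
#'   fold_change, p_value, low_power) and `within_case` (stratum, reference,
#'   n, n_ref, p_value).
#' @export
stratified_compare <- function(ratios, table, stratum_key,
                               reference = NULL, known_levels = NULL) {
  stopifnot(stratum_key %in% names(table))
  m <- merge(ratios, table, by = "sample_id")
  m <- m[!is.na(m$ratio), , drop = FALSE]
  strat <- as.character(m[[stratum_key]])
  if (!is.null(known_levels)) {
    unknown <- !strat %in% known_levels & !is.na(strat)
    if (any(unknown)) {
      warning(sprintf("%d sample(s) with unknown %s grouped under 'other'",
                      sum(unknown), stratum_key))
      strat[unknown] <- "other"
    }
  }
  m$.stratum <- strat
  m <- m[!is.na(m$.stratum), , drop = FALSE]
  levels_seen <- unique(m$.stratum)
  if (is.null(reference))
    reference <- if ("MM" %in% levels_seen) "MM" else levels_seen[1]

  per <- lapply(levels_seen, function(s) {
    sub <- m[m$.stratum == s, ]
    case <- sub$ratio[sub$group == "case"]
    ctrl <- sub$ratio[sub$group == "control"]
    if (length(case) == 0 || length(ctrl) == 0) {
      tibble::tibble(stratum = s, n_case = length(case),
                     n_control = length(ctrl), fold_change = NA_real_,
                     p_value = NA_real_, low_power = TRUE)
    } else {
      cc <- compare_cohorts(case, ctrl)
      tibble::tibble(stratum = s, n_case = cc$n_case, n_control = cc$n_control,
                     fold_change = cc$fold_change, p_value = cc$p_value,
                     low_power = cc$n_case < 2 || cc$n_control < 2)
    }
  })
  ref_case <- m$ratio[m$group == "case" & m$.stratum == reference]
  others <- setdiff(levels_seen, reference)
  wc <- lapply(others, function(s) {
    case_s <- m$ratio[m$group == "case" & m$.stratum == s]
    p <- if (length(case_s) >= 1 && length(ref_case) >= 1)
      rank_test_p(case_s, ref_case) else NA_real_
    tibble::tibble(stratum = s, reference = reference, n = length(case_s),
                   n_ref = length(ref_case), p_value = p)
  })
  list(per_stratum = do.call(rbind, per),
       within_case = if (length(wc)) do.call(rbind, wc)
                     else tibble::tibble(stratum = character(0),
                                         reference = character(0),
                                         n = integer(0), n_ref = integer(0),
                                         p_value = numeric(0)))
}

#' Trend of the distal ratio across an ordinal disease stage
#'
#' Spearman rank correlation of ratio versus stage (e.g. GOLD spirometric
#' stage) with a two-sided p-value.
#'
#' @param ratios Numeric ratios (`NA` dropped pairwise).
#' @param ordinal_stage Ordinal stage per sample (integer-like).
#' @return List `rho`, `p_value`, `n`, `degenerate` (`TRUE` when the ratios
#'   are constant, in which case `rho = 0`, `p = 1`).
#' @export
trend_test <- function(ratios, ordinal_stage) {
  keep <- !is.na(ratios) & !is.na(ordinal_stage)
  r <- ratios[keep]; s <- as.numeric(ordinal_stage)[keep]
  if (length(unique(s)) < 3) stop("need at least 3 distinct stages")
  if (length(unique(r)) == 1)
    return(list(rho = 0, p_value = 1, n = length(r), degenerate = TRUE))
  ct <- suppressWarnings(stats::cor.test(r, s, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(r),
       degenerate = FALSE)
}

#' Summarize the distal ratio by subcellular fraction
#'
#' Median ratio per fraction plus the nuclear/cytoplasmic fold (the
#' nuclear-retention signature: a higher ratio in the nuclear fraction).
#' Samples with a missing fraction label are excluded.
#'
#' @param ratios Numeric ratios.
#' @param fraction Character vector of fraction labels (`"nuclear"`,
#'   `"cytoplasmic"`, `"whole"`, ...), same length as `ratios`.
#' @return List: `summary` tibble (fraction, n, median_ratio) and
#'   `nuclear_cytoplasmic_fold` (`NA` when either fraction is absent).
#' @examples
#' fraction_compare(c(0.4, 0.5, 0.1, 0.1),
#'                  c("nuclear", "nuclear", "cytoplasmic", "cytoplasmic"))
#' @export
fraction_compare <- function(ratios, fraction) {
  keep <- !is.na(ratios) & !is.na(fraction)
  r <- ratios[keep]; f <- as.character(fraction)[keep]
  if (length(r) == 0) stop("no samples with a fraction label and ratio")
  fr <- unique(f)
  summary <- tibble::tibble(
    fraction = fr,
    n = vapply(fr, function(x) sum(f == x), integer(1), USE.NAMES = FALSE),
    median_ratio = vapply(fr, function(x) stats::median(r[f == x]), numeric(1),
                          USE.NAMES = FALSE))
  fold <- if (all(c("nuclear", "cytoplasmic") %in% fr))
    unname(summary$median_ratio[summary$fraction == "nuclear"] /
             summary$median_ratio[summary$fraction == "cytoplasmic"])
  else NA_real_
  list(summary = summary, nuclear_cytoplasmic_fold = fold)
}

#' Per-cell distal ratios and per-cluster distributions
#'
#' Applies the same length-normalized ratio to single-cell region counts:
#' with `p` and `d` a cell's read counts in the proximal and distal segments,
#' `ratio = (d/Ld) / (d/Ld + p/Lp)`. Cells with fewer than `min_total_reads`
#' total region reads are excluded; clusters left with zero passing cells
#' are omitted with a warning.
#'
#' @param counts Matrix or data frame with columns `proximal` and `distal`
#'   (non-negative integer read counts), one row per cell; row names are
#'   cell ids when present.
#' @param clusters Cluster label per cell.
#' @param spec [region_spec()] supplying the two segment lengths.
#' @param min_total_reads Minimum total region reads to keep a cell
#'   (default 3).
#' @return List of tibbles `cells` (cell_id, cluster, proximal, distal,
#'   ratio) and `clusters` (cluster, n_cells, median_ratio, pooled_ratio —
#'   the pooled ratio sums counts across the cluster's passing cells before
#'   applying the same formula).
#' @export
single_cell_ratios <- function(counts, clusters,
                               spec = serpina1_region_spec(),
                               min_total_reads = 3) {
  counts <- as.data.frame(counts)
  stopifnot(all(c("proximal", "distal") %in% names(counts)),
            nrow(counts) == length(clusters))
  p <- as.numeric(counts$proximal); d <- as.numeric(counts$distal)
  if (any(p < 0) || any(d < 0) || any(p != round(p)) || any(d != round(d)))
    stop("counts must be non-negative integers")
  lp <- interval_length(spec$proximal); ld <- interval_length(spec$distal)
  ids <- if (!is.null(rownames(counts))) rownames(counts)
         else sprintf("cell%d", seq_len(nrow(counts)))
  keep <- (p + d) >= min_total_reads
  if (!any(keep)) {
    warning("no cells pass min_total_reads; empty output")
    return(list(cells = tibble::tibble(cell_id = character(0),
                                       cluster = character(0),
                                       proximal = numeric(0),
                                       distal = numeric(0),
                                       ratio = numeric(0)),
                clusters = tibble::tibble(cluster = character(0),
                                          n_cells = integer(0),
                                          median_ratio = numeric(0),
                                          pooled_ratio = numeric(0))))
  }
  dropped_clusters <- setdiff(unique(as.character(clusters)),
                              unique(as.character(clusters)[keep]))
  if (length(dropped_clusters))
    warning(sprintf("cluster(s) with zero passing cells omitted: %s",
                    paste(dropped_clusters, collapse = ", ")))
  p <- p[keep]; d <- d[keep]; ids <- ids[keep]
  cl <- as.character(clusters)[keep]
  dn <- d / ld; pn <- p / lp
  cells <- tibble::tibble(cell_id = ids, cluster = cl, proximal = p,
                          distal = d, ratio = dn / (dn + pn))
  ucl <- unique(cl)
  clusters_tbl <- tibble::tibble(
    cluster = ucl,
    n_cells = vapply(ucl, function(x) sum(cl == x), integer(1),
                     USE.NAMES = FALSE),
    median_ratio = vapply(ucl, function(x) stats::median(cells$ratio[cl == x]),
                          numeric(1), USE.NAMES = FALSE),
    pooled_ratio = vapply(ucl, function(x) {
      dd <- sum(d[cl == x]) / ld; pp <- sum(p[cl == x]) / lp
      dd / (dd + pp)
    }, numeric(1), USE.NAMES = FALSE))
  list(cells = cells, clusters = clusters_tbl)
}
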