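# Volcano displacements for one or more records: dx = log2 differential
# expression fold change in disease, dy = knockdown distal ratio minus the
# empty-vector control ratio.
rbp_displacement <- function(de_lfc, kd_ratio, control_ratio) {
  stopifnot(control_ratio > 0, control_ratio < 1)
  list(dx = de_lfc, dy = kd_ratio - control_ratio)
}

#' Predicted direction of an RBP's effect on the disease distal ratio
#'
#' The knockdown displacement `dy = kd_ratio - control_ratio` shows what
#' *less* of the protein does to the distal ratio. When the protein is
#' down-regulated in disease (`dx = de_lfc < 0`), the disease effect shares
#' dy's sign; up-regulation flips it. Hence: `increase` when `dx*dy < 0`,
#' `decrease` when `dx*dy > 0`, `null` when either displacement is zero.
#' This is the quadrant rule of the two-dimensional volcano: e.g. a protein
#' in the bottom-left quadrant (down-regulated, knockdown lowers the ratio)
#' decreases the distal ratio in disease.
#'
#' @param de_lfc log2 differential-expression fold change (disease vs
#'   control); vectorized.
#' @param kd_ratio Distal ratio under shRNA knockdown; vectorized.
#' @param control_ratio Empty-vector control distal ratio (in `(0, 1)`).
#' @return Character vector: `"increase"`, `"decrease"` or `"null"`.
#' @examples
#' classify_direction(-0.13, 0.036, 0.07) # "decrease" (QKI-like)
#' @export
classify_direction <- function(de_lfc, kd_ratio, control_ratio) {
  d <- rbp_displacement(de_lfc, kd_ratio, control_ratio)
  prod <- d$dx * d$dy
  ifelse(prod < 0, "increase", ifelse(prod > 0, "decrease", "null"))
}

#' Signed log2 Euclidean effect distance from the volcano center
#'
#' Distance `d = sqrt(dx^2 + dy^2)` on the raw axes, scored as
#' `s * log2(d)` with `s = +1` for increase, `-1` for decrease, `0` for
#' null (and score 0 when `d = 0`). Ranking and candidate selection use
#' `|log2(d)|`, which is independent of the sign convention.
#'
#' @inheritParams classify_direction
#' @return Tibble: `direction`, `distance`, `log2_distance`, `signed_score`.
#' @export
effect_distance <- function(de_lfc, kd_ratio, control_ratio) {
  disp <- rbp_displacement(de_lfc, kd_ratio, control_ratio)
  dist <- sqrt(disp$dx^2 + disp$dy^2)
  direction <- classify_direction(de_lfc, kd_ratio, control_ratio)
  s <- ifelse(direction == "increase", 1, ifelse(direction == "decrease", -1, 0))
  l2 <- ifelse(dist > 0, log2(dist), NA_real_)
  score <- ifelse(dist == 0, 0, s * l2)
  tibble::tibble(direction = direction, distance = dist,
                 log2_distance = l2, signed_score = score)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (monotonized, so
#' adjusted values are order-preserving and never below the raw p-value).
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Select and rank RBP candidates from the two-dimensional volcano
#'
#' A record is significant when its (BH-adjusted) knockdown p-value and its
#' adjusted differential-expression p-value are both below `alpha` and the
#' absolute log2 Euclidean distance from the volcano center exceeds
#' `dist_threshold`. Output is ranked by `|signed_score|`, descending, with
#' increase/decrease counts among significant records attached.
#'
#' @param records Data frame with columns `name`, `kd_ratio`, `kd_p`,
#'   `de_lfc`, `de_padj` (an optional `kd_padj` column is used as-is;
#'   otherwise `kd_p` is BH-adjusted across the record set).
#' @param control_ratio Empty-vector control distal ratio.
#' @param dist_threshold Minimum `|log2(distance)|` (default 1).
#' @param alpha Significance level for both adjusted p-values (default
#'   0.05).
#' @return Tibble of all scored records (`name`, `direction`, `distance`,
#'   `log2_distance`, `signed_score`, `kd_padj`, `de_padj`, `significant`),
#'   sorted by `|signed_score|` descending, with attribute `counts`
#'   (named vector: increase/decrease among significant records).
#' @export
select_candidates <- function(records, control_ratio, dist_threshold = 1,
                              alpha = 0.05) {
  records <- as.data.frame(records)
  if (nrow(records) == 0) stop("records is empty")
  needed <- c("name", "kd_ratio", "kd_p", "de_lfc", "de_padj")
  missing_col <- setdiff(needed, names(records))
  if (length(missing_col))
    stop("missing column(s): ", paste(missing_col, collapse = ", "))
  ok <- stats::complete.cases(records[, needed])
  if (!all(ok)) {
    warning(sprintf("%d record(s) with missing fields skipped", sum(!ok)))
    records <- records[ok, , drop = FALSE]
  }
  kd_padj <- if ("kd_padj" %in% names(records)) records$kd_padj
             else bh_adjust(records$kd_p)
  eff <- effect_distance(records$de_lfc, records$kd_ratio, control_ratio)
  out <- tibble::tibble(name = records$name, direction = eff$direction,
                        distance = eff$distance,
                        log2_distance = eff$log2_distance,
                        signed_score = eff$signed_score,
                        kd_padj = kd_padj, de_padj = records$de_padj)
  out$significant <- out$kd_padj < alpha & out$de_padj < alpha &
    !is.na(out$log2_distance) & abs(out$log2_distance) > dist_threshold
  out <- out[order(-abs(out$signed_score)), , drop = FALSE]
  sig <- out[out$significant, , drop = FALSE]
  attr(out, "counts") <- c(increase = sum(sig$direction == "increase"),
                           decrease = sum(sig$direction == "decrease"))
  out
}
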