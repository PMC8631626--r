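#' Classify SHAPE reactivities into the standard three-color scheme
#'
#' High reactivity marks flexible (likely unpaired) nucleotides. Thresholds
#' follow the standard SHAPE coloring convention: `r >= 0.85` high,
#' `0.4 <= r < 0.85` intermediate, `r < 0.4` low (background-corrected
#' reactivities may be negative); missing values map to `"nodata"`.
#'
#' @param r Numeric reactivities (`NA` = no data); vectorized.
#' @param thresholds Length-2 numeric `c(intermediate, high)` boundaries
#'   (default `c(0.4, 0.85)`), each owned by the upper class.
#' @return Character vector in
#'   `{"low", "intermediate", "high", "nodata"}`.
#' @export
classify_reactivity <- function(r, thresholds = c(0.4, 0.85)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  out <- ifelse(is.na(r), "nodata",
         ifelse(r >= thresholds[2], "high",
         ifelse(r >= thresholds[1], "intermediate", "low")))
  out
}

#' Per-nucleotide Shannon entropy of base-pairing probabilities
#'
#' `H_i = -sum_j P[i, j] * log10(P[i, j])` over pairing partners only (with
#' `0 * log 0 = 0`); low entropy marks nucleotides committed to a single
#' well-defined structure. The unpaired probability (`1 - rowSums(P)`) is
#' excluded by default, the common convention for structure-entropy tracks;
#' `include_unpaired = TRUE` adds its term.
#'
#' @param P Square symmetric matrix of pairing probabilities, entries in
#'   `[0, 1]`, row sums at most 1.
#' @param include_unpaired Include the unpaired-probability term (default
#'   `FALSE`).
#' @return Numeric vector of per-nucleotide entropies (log base 10).
#' @examples
#' P <- matrix(0, 3, 3); P[1, 2] <- P[2, 1] <- 0.5; P[1, 3] <- P[3, 1] <- 0.5
#' shannon_entropy(P)[1] # 0.30103
#' @export
shannon_entropy <- function(P, include_unpaired = FALSE) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("P must be square")
  if (any(is.na(P)) || any(P < 0) || any(P > 1))
    stop("P entries must be in [0, 1]")
  if (max(abs(P - t(P))) > 1e-8) stop("P must be symmetric")
  rs <- rowSums(P)
  if (any(rs > 1 + 1e-8)) stop("row sums must not exceed 1")
  plogp <- function(p) ifelse(p > 0, p * log10(p), 0)
  H <- -rowSums(plogp(P))
  if (include_unpaired) H <- H - plogp(pmax(1 - rs, 0))
  H
}

#' Accessibility of a motif site from SHAPE reactivities
#'
#' Median reactivity over the site's non-missing nucleotides; the site is
#' called accessible when the median reaches the intermediate-reactivity
#' boundary (default 0.4). At least half the site must have data.
#'
#' @param shape Numeric per-nucleotide reactivity profile (`NA` = no data).
#' @param site Integer positions of the site within the profile (e.g.
#'   `120:140`), or a length-2 vector taken as an inclusive range.
#' @param threshold Accessibility threshold on the median (default 0.4).
#' @param min_frac_present Minimum fraction of non-missing site nucleotides
#'   (default 0.5).
#' @return List: `median_reactivity`, `accessible`, `nodata` (TRUE when too
#'   few nucleotides have data).
#' @export
motif_accessibility <- function(shape, site, threshold = 0.4,
                                min_frac_present = 0.5) {
  if (length(site) == 2 && site[2] > site[1] + 1) site <- site[1]:site[2]
  if (any(site < 1) || any(site > length(shape)))
    stop("site positions outside the reactivity profile")
  vals <- shape[site]
  if (mean(!is.na(vals)) < min_frac_present)
    return(list(median_reactivity = NA_real_, accessible = NA, nodata = TRUE))
  med <- stats::median(vals, na.rm = TRUE)
  list(median_reactivity = med, accessible = med >= threshold, nodata = FALSE)
}
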