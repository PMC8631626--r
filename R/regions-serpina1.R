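#' Published SERPINA1 3'UTR region table
#'
#' The published coordinates of the proximal segment and the four distal
#' subregions of the SERPINA1 3'UTR (NM_000295, minus strand of chr14),
#' together with the published per-region translation coefficients and
#' standard errors. Transcript coordinates are 1-based inclusive; genomic
#' coordinates are reproduced exactly as printed (1-based inclusive, listed
#' in the orientation of the source, which for this minus-strand gene is
#' usually descending). Note the printed genomic spans are internally
#' inconsistent with the transcript spans for Region 1 (see
#' [check_table_coordinates()]); the packaged [serpina1_region_spec()] is
#' therefore derived from the transcript coordinates.
#'
#' @return A tibble with one row per region: `region`, `tx_start`, `tx_end`,
#'   `g_first`, `g_second` (genomic endpoints as printed), `coef`, `se`.
#' @export
serpina1_region_table <- function() {
  tibble::tibble(
    region   = c("Proximal", "Region1", "Region2", "Region3", "Region4"),
    tx_start = c(1519, 1619, 2017, 2417, 2817),
    tx_end   = c(1597, 2016, 2416, 2816, 3220),
    g_first  = c(94378451, 94377952, 94377953, 94377555, 94377157),
    g_second = c(94378373, 94378350, 94377554, 94377156, 94376747),
    coef     = c(NA, 0.34, 0.08, 0.22, 0.32),
    se       = c(NA, 0.04, 0.05, 0.05, 0.04)
  )
}

#' Check the published region table for internal consistency
#'
#' Compares, for each region, the length implied by the published transcript
#' coordinates with the length implied by the published genomic coordinates.
#' The converter never silently "fixes" published values; this reports where
#' they disagree (in the SERPINA1 table, Region 1 spans 398 transcript nt but
#' 399 genomic nt as printed).
#'
#' @param table A tibble in the layout of [serpina1_region_table()].
#' @return The table with added `tx_len`, `g_len` and `length_mismatch`
#'   columns.
#' @export
check_table_coordinates <- function(table = serpina1_region_table()) {
  tx_len <- as.integer(table$tx_end - table$tx_start + 1)
  g_len  <- as.integer(abs(table$g_second - table$g_first) + 1)
  out <- table
  out$tx_len <- tx_len
  out$g_len <- g_len
  out$length_mismatch <- tx_len != g_len
  out
}

#' Default SERPINA1 3'UTR region specification
#'
#' Builds the packaged [region_spec()] for SERPINA1 (minus strand, chr14).
#' All genomic intervals are derived from the published *transcript*
#' coordinates via [map_transcript_to_genomic()] anchored at transcript
#' position 1519 <-> chr14:94378451 — the published proximal-row anchor —
#' because the published genomic spans are not self-consistent (see
#' [check_table_coordinates()]). Derived this way, the proximal segment is
#' 79 bp and Regions 1-4 tile a 1602 bp distal segment exactly. The distal
#' interval is the union of Regions 1-4; both segments can be overridden by
#' any BED-supplied [region_spec()].
#'
#' @return A `region_spec` with subregions `Region1`..`Region4`.
#' @examples
#' spec <- serpina1_region_spec()
#' interval_length(spec$proximal) # 79
#' interval_length(spec$distal)   # 1602
#' @export
serpina1_region_spec <- function() {
  anchor_t <- 1519
  anchor_g <- 94378451
  tab <- serpina1_region_table()
  map1 <- function(row) {
    map_transcript_to_genomic(
      transcript_interval("NM_000295", tab$tx_start[row], tab$tx_end[row]),
      anchor_t, anchor_g, "-", chrom = "chr14")
  }
  proximal <- map1(1)
  subs <- lapply(2:5, map1)
  names(subs) <- tab$region[2:5]
  distal <- genomic_interval("chr14",
                             min(vapply(subs, function(s) s$start, numeric(1))),
                             max(vapply(subs, function(s) s$end, numeric(1))),
                             "-")
  region_spec("SERPINA1", proximal, distal, subregions = subs)
}

#' Published SERPINA1 per-region translation coefficients
#'
#' The four published translation coefficients (t1..t4 for Regions 1-4) used
#' as simulation truth and worked-example inputs throughout the package.
#'
#' @return Named numeric vector `c(Region1 = 0.34, Region2 = 0.08,
#'   Region3 = 0.22, Region4 = 0.32)`.
#' @export
serpina1_translation_coefficients <- function() {
  c(Region1 = 0.34, Region2 = 0.08, Region3 = 0.22, Region4 = 0.32)
}
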