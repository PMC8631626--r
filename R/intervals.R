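#' Genomic interval (0-based, half-open, plus-reference-strand coordinates)
#'
#' The package keeps a single internal coordinate convention: 0-based
#' half-open intervals on the + reference strand, with a `strand` field
#' recording the transcript orientation. Published 1-based inclusive
#' coordinates (including minus-strand coordinates listed in descending
#' genomic order, as in the SERPINA1 region table) are converted at the
#' boundary; see [map_transcript_to_genomic()].
#'
#' @param chrom Chromosome name, e.g. `"chr14"`.
#' @param start 0-based inclusive start position (`>= 0`).
#' @param end Exclusive end position; `end > start`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `genomic_interval`.
#' @examples
#' genomic_interval("chr14", 94378372L, 94378451L, "-")
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (is.na(start) || is.na(end) || start < 0 || end <= start)
    stop("invalid genomic interval: need 0 <= start < end")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' Transcript interval (1-based, inclusive)
#'
#' @param transcript_id Accession string, e.g. `"NM_000295"`.
#' @param start,end 1-based inclusive transcript positions, `1 <= start <= end`.
#' @return An object of class `transcript_interval`.
#' @export
transcript_interval <- function(transcript_id, start, end) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 1 || end < start)
    stop("invalid transcript interval: need 1 <= start <= end")
  structure(list(transcript_id = transcript_id, start = start, end = end),
            class = "transcript_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> %s:%s-%s (%s) [0-based half-open, %d bp]\n",
              x$chrom, format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE), x$strand,
              as.integer(x$end - x$start)))
  invisible(x)
}

#' @export
print.transcript_interval <- function(x, ...) {
  cat(sprintf("<transcript_interval> %s:%d-%d [1-based inclusive, %d nt]\n",
              x$transcript_id, as.integer(x$start), as.integer(x$end),
              as.integer(x$end - x$start + 1)))
  invisible(x)
}

#' Interval length in bases
#'
#' Half-open genomic intervals have length `end - start`; 1-based inclusive
#' transcript intervals have length `end - start + 1`. A bare numeric pair is
#' treated as published 1-based inclusive endpoints and is direction-agnostic
#' (`abs(diff) + 1`), so descending minus-strand coordinate pairs work as
#' printed.
#'
#' @param iv A `genomic_interval`, `transcript_interval`, or numeric pair of
#'   1-based inclusive endpoints in either order.
#' @return Integer number of bases.
#' @examples
#' interval_length(transcript_interval("NM_000295", 1519, 1597)) # 79
#' interval_length(c(94378451, 94378373))                        # 79
#' @export
interval_length <- function(iv) UseMethod("interval_length")

#' @export
interval_length.genomic_interval <- function(iv) as.integer(iv$end - iv$start)

#' @export
interval_length.transcript_interval <- function(iv)
  as.integer(iv$end - iv$start + 1)

#' @export
interval_length.numeric <- function(iv) {
  if (length(iv) != 2L || anyNA(iv)) stop("need two non-missing endpoints")
  as.integer(abs(iv[2] - iv[1]) + 1)
}

#' Map a transcript interval to genomic coordinates
#'
#' Maps 1-based inclusive transcript coordinates to a 0-based half-open
#' genomic interval through a single anchor pair (one transcript position and
#' its genomic position, both 1-based). For the minus strand, genomic
#' position = `anchor_genomic_pos - (transcript position - anchor_transcript_pos)`;
#' for the plus strand the offset is added. Only single-exon (contiguous)
#' mapping is supported — the SERPINA1 3'UTR lies entirely within its last
#' exon.
#'
#' @param t_iv A [transcript_interval()].
#' @param anchor_transcript_pos 1-based transcript position of the anchor.
#' @param anchor_genomic_pos 1-based genomic position corresponding to it.
#' @param strand `"+"` or `"-"`.
#' @param chrom Chromosome name for the result (default `"chr14"`).
#' @return A [genomic_interval()] of the same length.
#' @examples
#' # SERPINA1 proximal segment: NM_000295:1519-1597 <-> chr14:94378451-94378373
#' map_transcript_to_genomic(transcript_interval("NM_000295", 1519, 1597),
#'                           1519, 94378451, "-")
#' @export
map_transcript_to_genomic <- function(t_iv, anchor_transcript_pos,
                                      anchor_genomic_pos, strand,
                                      chrom = "chr14") {
  stopifnot(inherits(t_iv, "transcript_interval"))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (strand == "-") {
    g_hi <- anchor_genomic_pos - (t_iv$start - anchor_transcript_pos)
    g_lo <- anchor_genomic_pos - (t_iv$end - anchor_transcript_pos)
  } else {
    g_lo <- anchor_genomic_pos + (t_iv$start - anchor_transcript_pos)
    g_hi <- anchor_genomic_pos + (t_iv$end - anchor_transcript_pos)
  }
  if (g_lo < 1) stop("mapped genomic coordinates are non-positive")
  genomic_interval(chrom, g_lo - 1, g_hi, strand)
}

#' Map a genomic interval back to transcript coordinates
#'
#' Inverse of [map_transcript_to_genomic()] under the same anchor.
#'
#' @inheritParams map_transcript_to_genomic
#' @param g_iv A [genomic_interval()].
#' @param transcript_id Accession for the result.
#' @return A [transcript_interval()] of the same length.
#' @export
map_genomic_to_transcript <- function(g_iv, anchor_transcript_pos,
                                      anchor_genomic_pos,
                                      transcript_id = "tx") {
  stopifnot(inherits(g_iv, "genomic_interval"))
  g_lo <- g_iv$start + 1  # back to 1-based inclusive
  g_hi <- g_iv$end
  if (g_iv$strand == "-") {
    t_start <- anchor_transcript_pos + (anchor_genomic_pos - g_hi)
    t_end   <- anchor_transcript_pos + (anchor_genomic_pos - g_lo)
  } else {
    t_start <- anchor_transcript_pos + (g_lo - anchor_genomic_pos)
    t_end   <- anchor_transcript_pos + (g_hi - anchor_genomic_pos)
  }
  transcript_interval(transcript_id, t_start, t_end)
}

#' Strand-aware region specification for a two-site 3'UTR
#'
#' Bundles the proximal (short-isoform-specific) and distal
#' (long-isoform-specific) segments of a 3'UTR, plus optional named
#' subregions that tile the distal segment. "Downstream" always means 3' in
#' transcript direction: on the minus strand the distal segment has *lower*
#' genomic coordinates than the proximal one.
#'
#' @param gene Gene symbol.
#' @param proximal,distal [genomic_interval()]s on the same chromosome and
#'   strand; they must not overlap and distal must lie 3' of proximal in
#'   transcript direction.
#' @param subregions Optional named list of [genomic_interval()]s; when given
#'   they must tile the distal interval exactly (no gaps, no overlaps).
#' @return An object of class `region_spec`.
#' @seealso [serpina1_region_spec()] for the packaged SERPINA1 default.
#' @export
region_spec <- function(gene, proximal, distal, subregions = NULL) {
  stopifnot(inherits(proximal, "genomic_interval"),
            inherits(distal, "genomic_interval"))
  if (proximal$chrom != distal$chrom || proximal$strand != distal$strand)
    stop("proximal and distal must share chromosome and strand")
  if (proximal$start < distal$end && distal$start < proximal$end)
    stop("proximal and distal intervals overlap")
  downstream_ok <- if (proximal$strand == "-") distal$end <= proximal$start
                   else distal$start >= proximal$end
  if (!downstream_ok)
    stop("distal interval must lie 3' (downstream) of proximal in transcript direction")
  if (!is.null(subregions)) {
    stopifnot(is.list(subregions), !is.null(names(subregions)))
    for (sr in subregions) stopifnot(inherits(sr, "genomic_interval"))
    ord <- order(vapply(subregions, function(s) s$start, numeric(1)))
    srt <- subregions[ord]
    starts <- vapply(srt, function(s) s$start, numeric(1))
    ends   <- vapply(srt, function(s) s$end, numeric(1))
    if (starts[1] != distal$start || ends[length(ends)] != distal$end ||
        (length(srt) > 1 && any(starts[-1] != ends[-length(ends)])))
      stop("subregions must tile the distal interval without gaps or overlaps")
  }
  structure(list(gene = gene, strand = proximal$strand,
                 proximal = proximal, distal = distal,
                 subregions = subregions),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("<region_spec> %s (%s strand)\n", x$gene, x$strand))
  cat(sprintf("  proximal: %s:%s-%s (%d bp)\n", x$proximal$chrom,
              format(x$proximal$start, scientific = FALSE),
              format(x$proximal$end, scientific = FALSE),
              interval_length(x$proximal)))
  cat(sprintf("  distal:   %s:%s-%s (%d bp)\n", x$distal$chrom,
              format(x$distal$start, scientific = FALSE),
              format(x$distal$end, scientific = FALSE),
              interval_length(x$distal)))
  if (!is.null(x$subregions))
    cat(sprintf("  subregions: %s\n", paste(names(x$subregions), collapse = ", ")))
  invisible(x)
}

#' Per-base coverage track over a contiguous genomic span
#'
#' @param interval A [genomic_interval()].
#' @param depth Numeric vector of non-negative per-base depths, one per base,
#'   ordered by ascending genomic position.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(interval, depth) {
  stopifnot(inherits(interval, "genomic_interval"))
  depth <- as.numeric(depth)
  if (length(depth) != interval_length(interval))
    stop("depth length must equal interval length")
  if (anyNA(depth) || any(depth < 0)) stop("depth must be non-negative")
  structure(list(interval = interval, depth = depth), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s:%s-%s (%s), %d bases, mean depth %.2f\n",
              x$interval$chrom,
              format(x$interval$start, scientific = FALSE),
              format(x$interval$end, scientific = FALSE),
              x$interval$strand, length(x$depth), mean(x$depth)))
  invisible(x)
}

#' Per-base read 3'-end count track
#'
#' Same layout as [coverage_track()] but holding counts of read 3' ends
#' (cleavage evidence from 3'-end sequencing), which must be non-negative
#' integers.
#'
#' @inheritParams coverage_track
#' @param end_counts Non-negative integer counts, one per base.
#' @return An object of class `end_count_track`.
#' @export
end_count_track <- function(interval, end_counts) {
  stopifnot(inherits(interval, "genomic_interval"))
  end_counts <- as.numeric(end_counts)
  if (length(end_counts) != interval_length(interval))
    stop("end_counts length must equal interval length")
  if (anyNA(end_counts) || any(end_counts < 0) ||
      any(end_counts != round(end_counts)))
    stop("end_counts must be non-negative integers")
  structure(list(interval = interval, end_counts = end_counts),
            class = "end_count_track")
}

# Extract the depth slice of a coverage track falling inside `iv`.
# Errors if `iv` is not fully contained in the track's span.
track_slice <- function(track, iv) {
  ti <- track$interval
  if (iv$chrom != ti$chrom || iv$start < ti$start || iv$end > ti$end)
    stop(sprintf("interval %s:%s-%s not contained in coverage track span",
                 iv$chrom, format(iv$start, scientific = FALSE),
                 format(iv$end, scientific = FALSE)))
  idx <- seq.int(iv$start - ti$start + 1, iv$end - ti$start)
  track$depth[idx]
}
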