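# Sequence utilities shared by the scanners: uppercase, DNA T treated as
# RNA U throughout.
normalize_rna <- function(seq) chartr("Tt", "Uu", toupper(seq))

#' Reverse complement of a DNA/RNA string
#'
#' @param seq Character string (A/C/G/U/T/N; case-insensitive).
#' @return Reverse complement as an RNA-alphabet string (T reported as U).
#' @export
reverse_complement <- function(seq) {
  s <- normalize_rna(seq)
  comp <- chartr("ACGUN", "UGCAN", s)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

#' Call cleavage-site peaks from a 3'-end count track
#'
#' Greedy single-linkage clustering of read 3'-end positions: walking
#' 5' to 3' in transcript direction, successive non-zero positions at most
#' `merge_window` bases apart join one cluster. Clusters whose total count
#' falls below `min_count` are discarded (their reads are reported in the
#' `discarded_count` attribute so reads are conserved). The cluster summit is
#' the position of maximum count, ties broken toward the most 3' position in
#' transcript direction — matching the sharp 3' cliff expected at a cleavage
#' site.
#'
#' @param track An [end_count_track()].
#' @param min_count Minimum reads per retained cluster (default 10).
#' @param merge_window Maximum gap (nt) joining adjacent end positions
#'   (default 8).
#' @return Tibble of sites sorted 5' to 3' in transcript direction:
#'   `summit`, `total_count`, `span_start`, `span_end` (1-based inclusive
#'   genomic), with attribute `discarded_count`.
#' @export
call_end_peaks <- function(track, min_count = 10, merge_window = 8) {
  stopifnot(inherits(track, "end_count_track"),
            min_count >= 1, merge_window >= 0)
  iv <- track$interval
  pos <- which(track$end_counts > 0) + iv$start  # 1-based genomic
  empty <- tibble::tibble(summit = numeric(0), total_count = numeric(0),
                          span_start = numeric(0), span_end = numeric(0))
  if (length(pos) == 0) {
    attr(empty, "discarded_count") <- 0
    return(empty)
  }
  counts <- track$end_counts[pos - iv$start]
  # order in transcript direction (descending genomic on the minus strand)
  ord <- if (iv$strand == "-") order(-pos) else order(pos)
  pos <- pos[ord]; counts <- counts[ord]
  cluster_id <- cumsum(c(1, abs(diff(pos)) > merge_window))
  sites <- lapply(split(seq_along(pos), cluster_id), function(i) {
    p <- pos[i]; n <- counts[i]
    best <- which(n == max(n))
    summit <- p[best[length(best)]]  # last index = most 3' in transcript order
    tibble::tibble(summit = summit, total_count = sum(n),
                   span_start = min(p), span_end = max(p))
  })
  sites <- do.call(rbind, sites)
  keep <- sites$total_count >= min_count
  discarded <- sum(sites$total_count[!keep])
  sites <- sites[keep, , drop = FALSE]
  attr(sites, "discarded_count") <- discarded
  sites
}

#' Scan for polyadenylation-signal hexamers upstream of a cleavage position
#'
#' Reports every hexamer within `window_upstream` bases upstream of
#' `cleavage_pos` (the hexamer must lie entirely in
#' `[cleavage_pos - window_upstream, cleavage_pos - 1]`) at Hamming distance
#' at most 1 from the canonical signal `AAUAAA`. Canonical hits are listed
#' first, then single-mismatch variants by ascending distance from the
#' cleavage position. DNA input (T) is treated as U; positions are 1-based
#' within `seq`, which is read in transcript (5' to 3') orientation.
#'
#' @param seq Sequence string in transcript orientation.
#' @param cleavage_pos 1-based cleavage position within `seq`.
#' @param window_upstream Search window in nt (default 40); clipped to the
#'   sequence start.
#' @return Tibble: `hexamer`, `start` (1-based), `offset` (bases from
#'   hexamer start to cleavage position), `class`
#'   (`"canonical"`/`"variant"`).
#' @examples
#' scan_pas("GGGAAUAAAGGGGGGGGGGC", 20) # one canonical hit
#' @export
scan_pas <- function(seq, cleavage_pos, window_upstream = 40) {
  s <- normalize_rna(seq)
  n <- nchar(s)
  empty <- tibble::tibble(hexamer = character(0), start = integer(0),
                          offset = integer(0), class = character(0))
  if (n < 6) return(empty)
  lo <- max(1, cleavage_pos - window_upstream)
  hi <- min(cleavage_pos - 6, n - 5)
  if (hi < lo) return(empty)
  starts <- lo:hi
  hex <- substring(s, starts, starts + 5)
  ref <- strsplit("AAUAAA", "")[[1]]
  dist <- vapply(strsplit(hex, ""),
                 function(h) sum(h != ref), integer(1))
  keep <- dist <= 1
  out <- tibble::tibble(hexamer = hex[keep], start = starts[keep],
                        offset = as.integer(cleavage_pos - starts[keep]),
                        class = c("canonical", "variant")[dist[keep] + 1])
  out[order(out$class != "canonical", out$offset), , drop = FALSE]
}

#' Score a downstream region for G/U richness
#'
#' Slides windows of `min_len` nt across
#' `[cleavage_pos, cleavage_pos + window_downstream)` (clipped to the
#' sequence) and reports the maximum G/U fraction; the region is called
#' G/U-rich when that score reaches `min_frac`.
#'
#' @inheritParams scan_pas
#' @param window_downstream Downstream search span in nt (default 40).
#' @param min_frac Minimum G/U fraction to call the element (default 0.6).
#' @param min_len Window length in nt (default 10).
#' @return List: `gu_rich` (logical), `score` (best window G/U fraction;
#'   `NA` when no full window fits), `flag` (`"ok"` or
#'   `"no_downstream_sequence"`).
#' @export
scan_gu_rich <- function(seq, cleavage_pos, window_downstream = 40,
                         min_frac = 0.6, min_len = 10) {
  stopifnot(window_downstream > 0, min_len > 0)
  s <- normalize_rna(seq)
  n <- nchar(s)
  last_start <- min(cleavage_pos + window_downstream - min_len, n - min_len + 1)
  if (cleavage_pos > last_start || cleavage_pos > n)
    return(list(gu_rich = FALSE, score = NA_real_,
                flag = "no_downstream_sequence"))
  starts <- cleavage_pos:last_start
  score <- max(vapply(starts, function(p) {
    w <- strsplit(substr(s, p, p + min_len - 1), "")[[1]]
    mean(w %in% c("G", "U"))
  }, numeric(1)))
  list(gu_rich = score >= min_frac, score = score, flag = "ok")
}

# TRUE where seq[i..i+6] matches NACUAAY (N any base, Y in {C, U}).
qki_half1_at <- function(chars, i) {
  all(chars[i + 1:5] == c("A", "C", "U", "A", "A")) &&
    chars[i + 6] %in% c("C", "U")
}

# TRUE where seq[j..j+3] matches UAAY.
qki_half2_at <- function(chars, j) {
  all(chars[j + 0:2] == c("U", "A", "A")) && chars[j + 3] %in% c("C", "U")
}

#' Scan for the bipartite QKI binding motif
#'
#' Finds occurrences of the consensus `5'-NACUAAY-N(1,20)-UAAY-3'` (Y = C or
#' U, N = any base): a 7-nt half-site followed, after a spacer of 1-20 nt,
#' by a 4-nt `UAAY` half-site. The default policy pairs each half-site with
#' its nearest downstream closer (shortest spacer) and forbids half-sites
#' from overlapping a previously matched half-site; `"exhaustive"` mode
#' reports every valid pairing.
#'
#' @param seq Sequence string (transcript orientation; T treated as U).
#' @param mode `"shortest_spacer"` (default) or `"exhaustive"`.
#' @param min_spacer,max_spacer Spacer length bounds (defaults 1 and 20).
#' @return Tibble: `half1_start`, `spacer_len`, `half2_start` (1-based),
#'   `half1_seq`, `half2_seq`, satisfying
#'   `half2_start == half1_start + 7 + spacer_len`.
#' @examples
#' scan_qki_motif("GGAACUAACGGGGGUAAUGG") # AACUAAC ... GGGGG ... UAAU
#' @export
scan_qki_motif <- function(seq, mode = c("shortest_spacer", "exhaustive"),
                           min_spacer = 1, max_spacer = 20) {
  mode <- match.arg(mode)
  s <- normalize_rna(seq)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  out <- list()
  used <- logical(n)  # half-site occupancy, shortest-spacer mode only
  i <- 1
  while (i + 10 <= n) {  # need at least 7 + 1 + 4 remaining
    if (qki_half1_at(chars, i) &&
        (mode == "exhaustive" || !any(used[i:(i + 6)]))) {
      spacers <- min_spacer:max_spacer
      hit <- FALSE
      for (sp in spacers) {
        j <- i + 7 + sp
        if (j + 3 > n) break
        if (qki_half2_at(chars, j) &&
            (mode == "exhaustive" || !any(used[j:(j + 3)]))) {
          out[[length(out) + 1]] <- tibble::tibble(
            half1_start = as.integer(i), spacer_len = as.integer(sp),
            half2_start = as.integer(j),
            half1_seq = substr(s, i, i + 6),
            half2_seq = substr(s, j, j + 3))
          hit <- TRUE
          if (mode == "shortest_spacer") {
            used[c(i:(i + 6), j:(j + 3))] <- TRUE
            break
          }
        }
      }
    }
    i <- i + 1
  }
  if (length(out) == 0)
    return(tibble::tibble(half1_start = integer(0), spacer_len = integer(0),
                          half2_start = integer(0), half1_seq = character(0),
                          half2_seq = character(0)))
  do.call(rbind, out)
}

#' Annotate called cleavage sites with PAS and G/U-rich elements
#'
#' Convenience wrapper: converts each site summit to a position in a
#' transcript-oriented sequence of the track interval, then runs
#' [scan_pas()] upstream and [scan_gu_rich()] downstream of it.
#'
#' @param sites Output of [call_end_peaks()].
#' @param seq Sequence of the track interval, in transcript (5' to 3')
#'   orientation.
#' @param interval The [genomic_interval()] the track and `seq` cover.
#' @param ... Passed to [scan_pas()] and [scan_gu_rich()].
#' @return `sites` with added columns `seq_pos`, `pas_hexamer`, `pas_class`,
#'   `pas_offset`, `gu_rich`, `gu_score`.
#' @export
annotate_cleavage_sites <- function(sites, seq, interval, ...) {
  stopifnot(inherits(interval, "genomic_interval"))
  if (nchar(seq) != interval_length(interval))
    stop("sequence length must match interval length")
  seq_pos <- if (interval$strand == "-") interval$end - sites$summit + 1
             else sites$summit - interval$start
  ann <- lapply(seq_pos, function(p) {
    pas <- scan_pas(seq, p)
    gu <- scan_gu_rich(seq, p)
    tibble::tibble(
      seq_pos = p,
      pas_hexamer = if (nrow(pas)) pas$hexamer[1] else NA_character_,
      pas_class = if (nrow(pas)) pas$class[1] else NA_character_,
      pas_offset = if (nrow(pas)) pas$offset[1] else NA_integer_,
      gu_rich = gu$gu_rich, gu_score = gu$score)
  })
  cbind(sites, do.call(rbind, ann))
}

#' Write called cleavage sites as BED
#'
#' The 5'-most site in transcript order is named `proximal` and the 3'-most
#' `distal` when exactly two sites are present; otherwise sites are named
#' `site1..siteN` in transcript order. The BED score carries the cluster
#' read count.
#'
#' @param sites Output of [call_end_peaks()] (already in transcript order).
#' @param path Output path.
#' @param chrom,strand Coordinates metadata for the BED records.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path, chrom = "chr14", strand = "-") {
  nm <- if (nrow(sites) == 2) c("proximal", "distal")
        else sprintf("site%d", seq_len(nrow(sites)))
  df <- data.frame(chrom = chrom,
                   start = format(sites$span_start - 1, scientific = FALSE, trim = TRUE),
                   end = format(sites$span_end, scientific = FALSE, trim = TRUE),
                   name = nm, score = sites$total_count, strand = strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
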