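#' Read per-base coverage for an interval from bedGraph or position/depth TSV
#'
#' Fills every base of `iv` with a depth: bases absent from the source get 0.
#' bedGraph parsing goes through `rtracklayer`; a light pre-scan reports the
#' line number of any malformed record first. The position/depth TSV dialect
#' has two columns (1-based genomic position, depth), with an optional header.
#'
#' @param source Path to a bedGraph (`.bedgraph`/`.bg`) or two-column TSV.
#' @param iv [genomic_interval()] to extract.
#' @param format `"auto"` (by extension, default), `"bedgraph"` or `"tsv"`.
#' @param strict If `TRUE`, fractional bedGraph values are rejected;
#'   otherwise they are rounded to the nearest integer.
#' @return A [coverage_track()] over `iv`.
#' @details Overlapping bedGraph records are an error (the depth of a base
#'   would be ambiguous). An interval on a chromosome absent from the source
#'   yields an all-zero track with a warning.
#' @export
read_coverage <- function(source, iv,
                          format = c("auto", "bedgraph", "tsv"),
                          strict = FALSE) {
  stopifnot(inherits(iv, "genomic_interval"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(bedgraph|bg)$", source, ignore.case = TRUE))
      "bedgraph" else "tsv"
  }
  depth <- numeric(interval_length(iv))
  if (format == "bedgraph") {
    check_bedgraph_lines(source)
    gr <- rtracklayer::import(source, format = "bedGraph")
    df <- as.data.frame(gr)  # start/end 1-based inclusive
    df <- df[as.character(df$seqnames) == iv$chrom, , drop = FALSE]
    if (nrow(df) == 0) {
      warning(sprintf("no records on %s; returning all-zero coverage", iv$chrom))
      return(coverage_track(iv, depth))
    }
    df <- df[order(df$start), , drop = FALSE]
    if (nrow(df) > 1 && any(df$start[-1] <= df$end[-nrow(df)]))
      stop("overlapping bedGraph records")
    if (any(df$score != round(df$score))) {
      if (strict) stop("fractional bedGraph values in strict mode")
      df$score <- round(df$score)
    }
    # convert records to 0-based half-open, clip to iv, fill
    for (k in seq_len(nrow(df))) {
      lo <- max(df$start[k] - 1, iv$start)
      hi <- min(df$end[k], iv$end)
      if (lo < hi)
        depth[seq.int(lo - iv$start + 1, hi - iv$start)] <- df$score[k]
    }
  } else {
    df <- read_position_depth_tsv(source)
    inside <- df$position > iv$start & df$position <= iv$end
    if (!any(inside) && nrow(df) > 0)
      warning("no positions inside the requested interval")
    d <- df[inside, , drop = FALSE]
    depth[d$position - iv$start] <- d$depth
  }
  coverage_track(iv, depth)
}

check_bedgraph_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || grepl("^(track|browser|#)", ln)) next
    f <- strsplit(trimws(ln), "[ \t]+")[[1]]
    bad <- length(f) < 4 ||
      anyNA(suppressWarnings(as.numeric(f[2:4]))) ||
      suppressWarnings(as.numeric(f[3])) <= suppressWarnings(as.numeric(f[2]))
    if (isTRUE(bad))
      stop(sprintf("malformed bedGraph line %d: '%s'", i, ln))
  }
  invisible(TRUE)
}

read_position_depth_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) == 0)
    return(data.frame(position = numeric(0), depth = numeric(0)))
  first <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  body <- if (has_header) lines[-1] else lines
  if (length(body) == 0)
    return(data.frame(position = numeric(0), depth = numeric(0)))
  parts <- strsplit(trimws(body), "[ \t]+")
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) < 2 ||
        anyNA(suppressWarnings(as.numeric(parts[[i]][1:2]))))
      stop(sprintf("malformed position/depth line %d: '%s'",
                   i + has_header, body[i]))
  }
  data.frame(position = vapply(parts, function(p) as.numeric(p[1]), numeric(1)),
             depth = vapply(parts, function(p) as.numeric(p[2]), numeric(1)))
}

#' Read a region specification from a BED file
#'
#' Expects BED records whose name field encodes the role: one `proximal`,
#' and either one `distal` record or subregion records (`Region1`,
#' `Region2`, ...) whose union defines the distal segment.
#'
#' @param path BED file path.
#' @param gene Gene label for the resulting spec.
#' @return A [region_spec()].
#' @export
read_region_bed <- function(path, gene = "gene") {
  df <- as.data.frame(rtracklayer::import(path, format = "BED"))
  if (is.null(df$name)) stop("BED name field required (proximal/distal/RegionN)")
  mk <- function(row) genomic_interval(as.character(df$seqnames[row]),
                                       df$start[row] - 1, df$end[row],
                                       as.character(df$strand[row]))
  prox_i <- which(tolower(df$name) == "proximal")
  if (length(prox_i) != 1) stop("need exactly one 'proximal' BED record")
  proximal <- mk(prox_i)
  sub_i <- grep("^region", tolower(df$name))
  dist_i <- which(tolower(df$name) == "distal")
  if (length(sub_i) > 0) {
    subs <- lapply(sub_i, mk)
    names(subs) <- df$name[sub_i]
    distal <- genomic_interval(proximal$chrom,
                               min(vapply(subs, `[[`, numeric(1), "start")),
                               max(vapply(subs, `[[`, numeric(1), "end")),
                               proximal$strand)
    region_spec(gene, proximal, distal, subregions = subs)
  } else if (length(dist_i) == 1) {
    region_spec(gene, proximal, mk(dist_i))
  } else stop("need a 'distal' record or RegionN records")
}

#' Write a region specification as BED6
#'
#' @param spec A [region_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(spec, path) {
  ivs <- c(list(proximal = spec$proximal, distal = spec$distal),
           spec$subregions)
  df <- data.frame(
    chrom = vapply(ivs, `[[`, character(1), "chrom"),
    start = format(vapply(ivs, `[[`, numeric(1), "start"), scientific = FALSE, trim = TRUE),
    end   = format(vapply(ivs, `[[`, numeric(1), "end"), scientific = FALSE, trim = TRUE),
    name  = names(ivs), score = 0,
    strand = vapply(ivs, `[[`, character(1), "strand"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readBStringSet()` returning plain named
#' character strings (DNA or RNA alphabets both pass through unchanged; the
#' motif scanners treat T and U interchangeably).
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}
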