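# Independent brute-force oracles used by the property tests. These stay
# deliberately naive (explicit loops, explicit pattern checks) and share no
# code with the package implementations they check.

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")

# Every hexamer fully inside [cleavage_pos - window, cleavage_pos - 1] at
# Hamming distance <= 1 from AAUAAA, canonical first then by offset.
oracle_pas <- function(seq, cleavage_pos, window = 40) {
  s <- chartr("Tt", "Uu", toupper(seq))
  n <- nchar(s)
  ref <- c("A", "A", "U", "A", "A", "A")
  hits <- list()
  for (start in 1:max(1, n)) {
    if (start + 5 > n) next
    if (start < cleavage_pos - window) next
    if (start + 5 > cleavage_pos - 1) next
    hex <- strsplit(substr(s, start, start + 5), "")[[1]]
    d <- 0
    for (k in 1:6) if (hex[k] != ref[k]) d <- d + 1
    if (d <= 1)
      hits[[length(hits) + 1]] <- data.frame(
        hexamer = paste(hex, collapse = ""), start = start,
        offset = cleavage_pos - start,
        class = if (d == 0) "canonical" else "variant")
  }
  if (!length(hits))
    return(data.frame(hexamer = character(0), start = integer(0),
                      offset = integer(0), class = character(0)))
  df <- do.call(rbind, hits)
  df[order(df$class != "canonical", df$offset), , drop = FALSE]
}

# All (half1, spacer) pairings of NACUAAY ... N(1,20) ... UAAY.
oracle_qki_exhaustive <- function(seq, min_spacer = 1, max_spacer = 20) {
  s <- chartr("Tt", "Uu", toupper(seq))
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  is_y <- function(x) x == "C" || x == "U"
  out <- list()
  for (i in seq_len(max(0, n - 10))) {
    if (!(ch[i + 1] == "A" && ch[i + 2] == "C" && ch[i + 3] == "U" &&
          ch[i + 4] == "A" && ch[i + 5] == "A" && is_y(ch[i + 6]))) next
    for (sp in min_spacer:max_spacer) {
      j <- i + 7 + sp
      if (j + 3 > n) break
      if (ch[j] == "U" && ch[j + 1] == "A" && ch[j + 2] == "A" &&
          is_y(ch[j + 3]))
        out[[length(out) + 1]] <- data.frame(half1_start = i, spacer_len = sp,
                                             half2_start = j)
    }
  }
  if (!length(out))
    return(data.frame(half1_start = integer(0), spacer_len = integer(0),
                      half2_start = integer(0)))
  do.call(rbind, out)
}

# Step-up BH by hand: sort, multiply by m/rank, cumulative min from the
# largest, cap at 1, restore input order.
oracle_bh <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (k in (m - 1):1) if (m > 1) adj[k] <- min(adj[k], adj[k + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Sum of per-base coverage by explicit per-base accumulation over bedGraph
# records given as a data.frame(start0, end0, value) in 0-based half-open
# coordinates, restricted to the 0-based half-open window [lo, hi).
oracle_coverage_total <- function(records, lo, hi) {
  total <- 0
  for (pos in seq(lo, hi - 1)) {
    for (k in seq_len(nrow(records))) {
      if (pos >= records$start0[k] && pos < records$end0[k]) {
        total <- total + records$value[k]
        break
      }
    }
  }
  total
}

# Write a bedGraph file from 0-based half-open records; returns the path.
write_bedgraph <- function(records, chrom = "chr14",
                           path = tempfile(fileext = ".bedgraph")) {
  writeLines(sprintf("%s\t%d\t%d\t%g", chrom, records$start0, records$end0,
                     records$value), path)
  path
}

# Small plus-strand two-region spec for fast synthetic tests.
toy_spec <- function() {
  region_spec("toy",
              proximal = genomic_interval("chr1", 100, 150, "+"),
              distal = genomic_interval("chr1", 200, 400, "+"))
}
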