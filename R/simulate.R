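# Negative-binomial per-base counts with mean mu and overdispersion phi
# (var = mu + phi*mu^2); phi = 0 degrades to Poisson.
rnb <- function(n, mu, phi) {
  if (n == 0) return(integer(0))
  if (phi > 0) stats::rnbinom(n, mu = mu, size = 1 / phi)
  else stats::rpois(n, lambda = mu)
}

#' Two-isoform coverage model
#'
#' Describes a transcript pool with a short isoform (abundance `S`,
#' covering only the proximal segment) and a long isoform (abundance `L`,
#' covering the whole 3'UTR). Because both isoforms cover the proximal
#' segment, the distal-ratio estimand under this model is `L / (S + 2L)`,
#' which is bounded above by 0.5.
#'
#' @param S,L Non-negative isoform abundances, `S + L > 0`.
#' @param spec [region_spec()] (default SERPINA1).
#' @param mean_depth Mean reads/base contributed by one abundance unit
#'   (`> 0`).
#' @param dispersion Negative-binomial overdispersion (default 0.1;
#'   0 = Poisson).
#' @return Object of class `isoform_model`.
#' @export
isoform_model <- function(S, L, spec = serpina1_region_spec(),
                          mean_depth = 100, dispersion = 0.1) {
  stopifnot(S >= 0, L >= 0, S + L > 0, mean_depth > 0, dispersion >= 0,
            inherits(spec, "region_spec"))
  structure(list(S = S, L = L, spec = spec, mean_depth = mean_depth,
                 dispersion = dispersion), class = "isoform_model")
}

#' True distal ratio of an isoform model
#'
#' Closed form of the estimand targeted by [compute_distal_ratio()] under
#' the two-isoform model: `L / (S + 2L)`.
#'
#' @param m An [isoform_model()], or the `S` abundance when `L` is given.
#' @param L Long-isoform abundance (when `m` is numeric).
#' @return The asymptotic distal ratio.
#' @export
true_distal_ratio <- function(m, L = NULL) {
  if (inherits(m, "isoform_model")) {
    L <- m$L; S <- m$S
  } else S <- m
  if (S + L == 0) return(NA_real_)
  L / (S + 2 * L)
}

# Invert r = L/(S+2L) with S fixed at 1: L = r/(1-2r). Valid for r < 0.5.
ratio_to_long_abundance <- function(r) {
  stopifnot(all(r >= 0), all(r < 0.5))
  r / (1 - 2 * r)
}

#' Simulate per-base 3'UTR coverage under the two-isoform model
#'
#' Per-base depth is negative-binomially distributed with mean
#' `mean_depth * (S + L)` inside the proximal segment and `mean_depth * L`
#' everywhere 3' of it (the long isoform covers the gap between the two
#' segments as well as the distal segment). Bit-reproducible under a fixed
#' seed.
#'
#' @param m An [isoform_model()].
#' @param seed Integer seed (required; generators keep no global state).
#' @return A [coverage_track()] spanning from the 5'-most to the 3'-most
#'   base of the model's regions.
#' @export
simulate_coverage <- function(m, seed) {
  stopifnot(inherits(m, "isoform_model"))
  withr::with_seed(seed, draw_coverage(m))
}

# Draw one coverage track using the current RNG state (shared by
# simulate_coverage and simulate_cohort, whose seed scopes differ).
draw_coverage <- function(m) {
  spec <- m$spec
  span <- genomic_interval(spec$proximal$chrom,
                           min(spec$proximal$start, spec$distal$start),
                           max(spec$proximal$end, spec$distal$end),
                           spec$strand)
  n <- interval_length(span)
  pos0 <- span$start + seq_len(n) - 1  # 0-based position of each base
  in_prox <- pos0 >= spec$proximal$start & pos0 < spec$proximal$end
  d <- numeric(n)
  d[in_prox] <- rnb(sum(in_prox), m$mean_depth * (m$S + m$L), m$dispersion)
  d[!in_prox] <- rnb(sum(!in_prox), m$mean_depth * m$L, m$dispersion)
  coverage_track(span, d)
}

#' Simulate a case/control cohort of coverage tracks with planted truth
#'
#' Control distal ratios are drawn from a Beta distribution; case ratios
#' from the same Beta scaled by `fold`, so the case population median is
#' `fold` times the control median. Each ratio is inverted to isoform
#' abundances (`S = 1`, `L = r/(1 - 2r)`) and passed through
#' [simulate_coverage()]. Ratios are capped at `max_ratio` (default 0.45)
#' with a warning, since the estimand cannot exceed 0.5 while both isoforms
#' share the proximal segment.
#'
#' @param n_case,n_control Cohort sizes (each at least 1).
#' @param fold Case/control ratio of population medians (default 2).
#' @param beta_shape1,beta_shape2 Control-ratio Beta parameters (defaults
#'   5 and 95: median about 0.047 with wide inter-individual spread).
#' @param spec [region_spec()] (default SERPINA1).
#' @param mean_depth Reads/base per abundance unit (default 50).
#' @param dispersion Negative-binomial overdispersion (default 0.1).
#' @param seed Integer seed.
#' @param max_ratio Cap on simulated true ratios (default 0.45).
#' @return List: `tracks` (named list of [coverage_track()]s), `truth`
#'   (tibble `sample_id`, `group`, `true_ratio`), `spec`.
#' @export
simulate_cohort <- function(n_case, n_control, fold = 2,
                            beta_shape1 = 5, beta_shape2 = 95,
                            spec = serpina1_region_spec(),
                            mean_depth = 50, dispersion = 0.1,
                            seed, max_ratio = 0.45) {
  if (n_case < 1 || n_control < 1) stop("need at least one sample per group")
  stopifnot(fold > 0)
  if (fold * stats::qbeta(0.5, beta_shape1, beta_shape2) >= 1)
    stop("fold pushes the case median ratio to 1 or beyond")
  withr::with_seed(seed, {
    r_ctrl <- stats::rbeta(n_control, beta_shape1, beta_shape2)
    r_case <- fold * stats::rbeta(n_case, beta_shape1, beta_shape2)
    r <- c(r_case, r_ctrl)
    if (any(r > max_ratio)) {
      warning(sprintf("%d simulated ratio(s) capped at %.2f", sum(r > max_ratio),
                      max_ratio))
      r <- pmin(r, max_ratio)
    }
    group <- rep(c("case", "control"), c(n_case, n_control))
    ids <- sprintf("%s%03d", group, c(seq_len(n_case), seq_len(n_control)))
    tracks <- lapply(r, function(ri) {
      draw_coverage(isoform_model(S = 1, L = ratio_to_long_abundance(ri),
                                  spec = spec, mean_depth = mean_depth,
                                  dispersion = dispersion))
    })
    names(tracks) <- ids
    list(tracks = tracks,
         truth = tibble::tibble(sample_id = ids, group = group,
                                true_ratio = r),
         spec = spec)
  })
}

#' Simulate a 3'-end count track around known cleavage sites
#'
#' Each read is assigned to a site multinomially by the usage fractions and
#' lands at the site position plus rounded Gaussian jitter (clamped to the
#' interval). Read counts are conserved: the track total equals `n_reads`.
#'
#' @param positions 1-based genomic site positions inside `interval`.
#' @param fractions Site usage fractions summing to 1.
#' @param n_reads Total reads.
#' @param interval [genomic_interval()] the track covers.
#' @param jitter_sd Gaussian position jitter in nt (default 2).
#' @param seed Integer seed.
#' @return An [end_count_track()].
#' @export
simulate_end_seq <- function(positions, fractions, n_reads, interval,
                             jitter_sd = 2, seed) {
  stopifnot(length(positions) == length(fractions),
            abs(sum(fractions) - 1) < 1e-8,
            inherits(interval, "genomic_interval"),
            all(positions > interval$start), all(positions <= interval$end))
  n_bases <- interval_length(interval)
  if (n_reads == 0) return(end_count_track(interval, numeric(n_bases)))
  counts <- withr::with_seed(seed, {
    site <- sample.int(length(positions), n_reads, replace = TRUE,
                       prob = fractions)
    pos <- positions[site] + round(stats::rnorm(n_reads, 0, jitter_sd))
    pos <- pmin(pmax(pos, interval$start + 1), interval$end)
    tabulate(pos - interval$start, nbins = n_bases)
  })
  end_count_track(interval, counts)
}

#' Simulate replicate reporter luminescence from a construct design
#'
#' Each replicate value is the linear predictor `sum_i t_i x_i` plus
#' Gaussian noise, truncated at 0. Values are generated on the normalized
#' 0-1 scale, so the output feeds [fit_region_coefficients()] directly (the
#' `normalized` column); each replicate is labelled as one batch.
#'
#' @param design A [construct_design()].
#' @param t_true True coefficient vector (length matching the design
#'   columns).
#' @param sigma Gaussian noise standard deviation (default 0.03).
#' @param n_replicates Replicates per construct (default 4).
#' @param seed Integer seed.
#' @return Data frame: `construct`, `batch`, `value`, `normalized`.
#' @export
simulate_luminescence <- function(design, t_true, sigma = 0.03,
                                  n_replicates = 4, seed) {
  stopifnot(inherits(design, "construct_design"),
            length(t_true) == ncol(design$x), sigma >= 0, n_replicates >= 1)
  mu <- as.numeric(design$x %*% t_true)
  constructs <- rownames(design$x)
  withr::with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_replicates), function(b) {
      v <- pmax(mu + stats::rnorm(length(mu), 0, sigma), 0)
      data.frame(construct = constructs, batch = b, value = v)
    }))
    out$normalized <- out$value
    out
  })
}

#' Default planted RBP effects (six decreasers, two increasers)
#'
#' Knockdown-displacement/fold-change pairs on the scale of the strongest
#' observed effects: each planted record has `|log2(distance)| > 1` and
#' vanishing p-values, so a correct scorer recovers exactly this 6/2 split.
#'
#' @return Tibble: `name`, `direction`, `dx` (log2 DE fold change), `dy`
#'   (knockdown ratio displacement).
#' @export
default_planted_rbp_effects <- function() {
  tibble::tibble(
    name = c(sprintf("DEC%d", 1:6), sprintf("INC%d", 1:2)),
    direction = c(rep("decrease", 6), rep("increase", 2)),
    dx = c(-0.13, -0.09, -0.20, 0.15, -0.25, 0.30, -0.18, -0.12),
    dy = c(-0.034, -0.025, -0.040, 0.030, -0.030, 0.025, 0.035, 0.028))
}

#' Simulate an RBP knockdown/differential-expression table with planted truth
#'
#' Emulates the 224-protein two-dimensional volcano design: `n_null`
#' null records scatter tightly around the center with uniform p-values,
#' while planted records receive their stated displacements with vanishing
#' p-values. Differential-expression p-values are BH-adjusted across the
#' whole table into `de_padj`.
#'
#' @param n_null Number of null records (default 216, mirroring 224 minus
#'   8 planted).
#' @param planted Tibble of planted effects (see
#'   [default_planted_rbp_effects()]); may have zero rows.
#' @param control_ratio Empty-vector control distal ratio (default 0.07).
#' @param seed Integer seed.
#' @return List: `records` (tibble `name`, `kd_ratio`, `kd_p`, `de_lfc`,
#'   `de_p`, `de_padj`) and `truth` (tibble `name`, `planted_direction`).
#' @export
simulate_rbp_table <- function(n_null = 216,
                               planted = default_planted_rbp_effects(),
                               control_ratio = 0.07, seed) {
  stopifnot(n_null >= 0, control_ratio > 0, control_ratio < 1)
  withr::with_seed(seed, {
    null_rec <- tibble::tibble(
      name = sprintf("NULL%03d", seq_len(n_null)),
      kd_ratio = pmin(pmax(control_ratio + stats::rnorm(n_null, 0, 0.008),
                           1e-3), 1 - 1e-3),
      kd_p = stats::runif(n_null),
      de_lfc = stats::rnorm(n_null, 0, 0.03),
      de_p = stats::runif(n_null))
    np <- nrow(planted)
    planted_rec <- tibble::tibble(
      name = planted$name,
      kd_ratio = pmin(pmax(control_ratio + planted$dy, 1e-3), 1 - 1e-3),
      kd_p = 10^-stats::runif(np, 20, 35),
      de_lfc = planted$dx,
      de_p = 10^-stats::runif(np, 8, 20))
    records <- rbind(null_rec, planted_rec)
    records$de_padj <- bh_adjust(records$de_p)
    truth <- tibble::tibble(
      name = records$name,
      planted_direction = c(rep("null", n_null), planted$direction))
    list(records = records, truth = truth)
  })
}
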