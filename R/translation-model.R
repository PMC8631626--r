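#' Deletion-construct design for the SERPINA1 3'UTR reporter series
#'
#' Builds the construct-by-region membership design: `x[c, i] = 1` when
#' Region i is *absent* (deleted) from construct c. Under the no-intercept
#' model this parameterization predicts 0 for the Long construct (all four
#' distal regions present, translation fully repressed) and the coefficient
#' sum for the Short construct (all four absent) — the only reading under
#' which a model with no intercept is consistent with Short being the
#' brightest construct.
#'
#' @param x Numeric 0/1 matrix (constructs x regions) with construct row
#'   names and region column names; see [serpina1_deletion_design()] for the
#'   packaged default.
#' @param luminescence Optional replicate luminescence table (see
#'   [normalize_luminescence()]).
#' @return Object of class `construct_design`.
#' @export
construct_design <- function(x, luminescence = NULL) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("design matrix needs construct row names and region column names")
  if (!all(x %in% c(0, 1))) stop("membership entries must be 0/1")
  structure(list(x = x, luminescence = luminescence),
            class = "construct_design")
}

#' Packaged eight-construct deletion design
#'
#' Short deletes all four distal regions, Long none, and the six deletion
#' constructs remove: Del1 regions 2+3+4, Del2 region 1, Del3 region 2,
#' Del4 region 3, Del5 regions 1+2, Del6 region 2 (with region 1 retained).
#' This composition satisfies the published constraints (Deletion 1 removes
#' Regions 2, 3 and 4; Deletions 5 and 6 both retain regions 3 and 4) and —
#' unlike compositions in which regions 3 and 4 are always deleted together —
#' gives a full-column-rank design so that all four translation coefficients
#' are identifiable.
#'
#' @return A [construct_design()] with an 8 x 4 membership matrix.
#' @export
serpina1_deletion_design <- function() {
  x <- rbind(Short = c(1, 1, 1, 1), Long = c(0, 0, 0, 0),
             Del1 = c(0, 1, 1, 1), Del2 = c(1, 0, 0, 0),
             Del3 = c(0, 1, 0, 0), Del4 = c(0, 0, 1, 0),
             Del5 = c(1, 1, 0, 0), Del6 = c(0, 1, 0, 0))
  colnames(x) <- paste0("Region", 1:4)
  construct_design(x)
}

#' Normalize reporter luminescence to the 0-1 scale
#'
#' Per batch, nanoluciferase/firefly ratios are divided by that batch's mean
#' Short-construct value, so the Short mean maps to 1; values exceeding it
#' are clipped to 1 and flagged. An alternative min-max mode rescales each
#' batch to span exactly `[0, 1]`.
#'
#' @param lum Data frame with columns `construct`, `batch`, and either
#'   `value` or both `nano` and `firefly` (in which case
#'   `value = nano/firefly`).
#' @param method `"short_mean"` (default) or `"minmax"`.
#' @param short_name Name of the reference construct (default `"Short"`).
#' @return `lum` with added columns `normalized` and `clipped`.
#' @export
normalize_luminescence <- function(lum, method = c("short_mean", "minmax"),
                                   short_name = "Short") {
  method <- match.arg(method)
  lum <- as.data.frame(lum)
  if (!"value" %in% names(lum)) {
    if (!all(c("nano", "firefly") %in% names(lum)))
      stop("need a 'value' column or both 'nano' and 'firefly'")
    lum$value <- lum$nano / lum$firefly
  }
  if (!"batch" %in% names(lum)) lum$batch <- 1L
  out <- lapply(split(lum, lum$batch), function(b) {
    if (method == "short_mean") {
      if (!any(b$construct == short_name))
        stop(sprintf("batch %s has no '%s' construct", b$batch[1], short_name))
      ref <- mean(b$value[b$construct == short_name])
      v <- b$value / ref
    } else {
      v <- (b$value - min(b$value)) / (max(b$value) - min(b$value))
    }
    b$clipped <- v > 1 | v < 0
    b$normalized <- pmin(pmax(v, 0), 1)
    b
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fit per-region translation coefficients (no-intercept OLS)
#'
#' Ordinary least squares of normalized expression on the region-absent
#' indicators with no intercept: `y ~ sum_i t_i x_i`. Each replicate is one
#' observation; construct means enter only the reported R-squared, computed
#' as the squared Pearson correlation between per-construct predicted and
#' mean observed expression (the predicted-vs-measured fit quality).
#' Negative fitted coefficients are reported but flagged.
#'
#' @param design A [construct_design()].
#' @param y Data frame with columns `construct` and `normalized` (e.g. from
#'   [normalize_luminescence()]), or a numeric vector named by construct.
#' @return Object of class `translation_coefficients`: `t` (named
#'   coefficients), `se`, `r_squared`, `negative_flag`, `fit` (the `lm`
#'   object).
#' @export
fit_region_coefficients <- function(design, y) {
  stopifnot(inherits(design, "construct_design"))
  if (is.numeric(y)) y <- data.frame(construct = names(y), normalized = y)
  missing_c <- setdiff(unique(y$construct), rownames(design$x))
  if (length(missing_c))
    stop("constructs absent from design: ", paste(missing_c, collapse = ", "))
  X <- design$x[match(y$construct, rownames(design$x)), , drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; unidentifiable region(s): ",
         paste(dep, collapse = ", "))
  }
  fit <- stats::lm(y$normalized ~ 0 + X)
  t_hat <- stats::setNames(stats::coef(fit), colnames(X))
  se <- stats::setNames(summary(fit)$coefficients[, "Std. Error"], colnames(X))
  constructs <- rownames(design$x)
  obs_mean <- vapply(constructs,
                     function(cn) mean(y$normalized[y$construct == cn]),
                     numeric(1))
  keep <- !is.na(obs_mean)
  pred <- as.numeric(design$x[keep, , drop = FALSE] %*% t_hat)
  r2 <- if (sum(keep) >= 2 && stats::sd(pred) > 0 && stats::sd(obs_mean[keep]) > 0)
    stats::cor(pred, obs_mean[keep])^2 else NA_real_
  structure(list(t = t_hat, se = se, r_squared = r2,
                 negative_flag = any(t_hat < 0), fit = fit),
            class = "translation_coefficients")
}

#' @export
print.translation_coefficients <- function(x, ...) {
  cat("<translation_coefficients>\n")
  for (i in seq_along(x$t))
    cat(sprintf("  %s: %.2f%s\n", names(x$t)[i], x$t[i],
                if (is.finite(x$se[i])) sprintf("±%.2f", x$se[i]) else ""))
  cat(sprintf("  R-squared (construct means): %.3f\n", x$r_squared))
  if (x$negative_flag) cat("  warning: negative coefficient(s) fitted\n")
  invisible(x)
}

#' Coefficient table in the published layout
#'
#' @param coefs A `translation_coefficients` object.
#' @return Tibble with columns `region`, `coefficient`, `se`, `formatted`
#'   (e.g. `"0.34±0.04"`).
#' @export
coefficients_table <- function(coefs) {
  tibble::tibble(region = names(coefs$t),
                 coefficient = unname(coefs$t),
                 se = unname(coefs$se),
                 formatted = sprintf("%.2f±%.2f", coefs$t, coefs$se))
}

#' Predict normalized expression for a membership row
#'
#' `sum_i t_i x_i`, clipped to `[0, 1]` for reporting (the raw linear
#' predictor is available with `clip = FALSE`). The Long construct (all
#' zeros) predicts 0 under the no-intercept model.
#'
#' @param t Named coefficient vector or `translation_coefficients` object.
#' @param x 0/1 membership row (region *absent* indicators), length 4.
#' @param clip Clip the prediction into `[0, 1]` (default `TRUE`).
#' @return Predicted normalized expression.
#' @examples
#' predict_expression(serpina1_translation_coefficients(), c(1, 1, 1, 1)) # 0.96
#' @export
predict_expression <- function(t, x, clip = TRUE) {
  if (inherits(t, "translation_coefficients")) t <- t$t
  stopifnot(length(x) == length(t), all(x %in% c(0, 1)))
  pred <- sum(t * x)
  if (clip) pred <- min(max(pred, 0), 1)
  pred
}

#' Fraction of translation repression attributable to a region subset
#'
#' `sum_{i in subset} t_i / sum_i t_i`. Requires non-negative coefficients
#' (a negative coefficient means the fit should be inspected before
#' attributing variance).
#'
#' @param t Named coefficient vector or `translation_coefficients` object.
#' @param subset Region names or indices.
#' @return Fraction in `[0, 1]`.
#' @examples
#' variance_attribution(serpina1_translation_coefficients(),
#'                      c("Region1", "Region3", "Region4")) # 0.9167
#' @export
variance_attribution <- function(t, subset) {
  if (inherits(t, "translation_coefficients")) t <- t$t
  if (any(t < 0))
    stop("negative coefficient(s); inspect the fit before attribution")
  total <- sum(t)
  if (total == 0) stop("all coefficients are zero; attribution undefined")
  sum(t[subset]) / total
}

#' qPCR delta-CT and relative expression level
#'
#' `delta_ct = CT_target - CT_reference`; relative level `2^(-delta_ct)`.
#' Vectorized over timepoints/samples; missing CT values propagate to
#' missing outputs.
#'
#' @param ct_target,ct_reference Positive cycle-threshold values.
#' @return Tibble with columns `delta_ct` and `relative_level`.
#' @examples
#' delta_ct(25, 20) # delta 5, relative level 1/32
#' @export
delta_ct <- function(ct_target, ct_reference) {
  stopifnot(length(ct_target) == length(ct_reference))
  if (any(ct_target <= 0, na.rm = TRUE) || any(ct_reference <= 0, na.rm = TRUE))
    stop("CT values must be positive")
  d <- ct_target - ct_reference
  tibble::tibble(delta_ct = d, relative_level = 2^(-d))
}
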