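#' Log10 transform for normality screening
#'
#' Elementwise base-10 logarithm of strictly positive weights; used to
#' screen organ-weight distributions for normality before choosing
#' nonparametric tests. Rejects non-positive values, reporting their
#' indices.
#'
#' @param x Numeric vector, all > 0.
#' @return `log10(x)`.
#' @export
log10_transform <- function(x) {
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad) > 0) {
    stop("log10 transform requires positive values; offending indices: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  log10(x)
}

.test_result <- function(statistic, df, p_value, method, adjustment = "none") {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), method = method,
                 adjustment = adjustment),
            class = "weight_test")
}

#' @export
print.weight_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.5g, df = %s, p = %.4g (adjustment: %s)\n",
              x$method, x$statistic, paste(x$df, collapse = ","),
              x$p_value, x$adjustment))
  invisible(x)
}

#' Shapiro-Wilk normality screen
#'
#' Thin validated wrapper around [stats::shapiro.test()]; a small p-value
#' signals departure from normality (the screen that motivates the
#' nonparametric comparisons downstream).
#'
#' @param x Numeric vector, 3 <= n <= 5000, non-constant.
#' @return A `weight_test` with the W statistic and p-value.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3) stop("Shapiro-Wilk requires n >= 3")
  if (stats::sd(x) == 0) stop("Shapiro-Wilk is undefined for a constant vector")
  sw <- stats::shapiro.test(x)
  .test_result(sw$statistic, length(x), sw$p.value, "Shapiro-Wilk")
}

#' Kruskal-Wallis rank sum comparison across ecosystems
#'
#' Tie-corrected H statistic referred to a chi-square distribution with
#' k - 1 degrees of freedom, via [stats::kruskal.test()]. The degenerate
#' case where every observation is identical returns H = 0, p = 1 rather
#' than failing: identical groups are maximally compatible with the null.
#'
#' @param groups Named list of numeric vectors (>= 2 non-empty groups,
#'   total n >= 3).
#' @return A `weight_test`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- groups[vapply(groups, length, 1L) > 0]
  if (length(groups) < 2) stop("need >= 2 non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3) stop("need total n >= 3")
  if (length(unique(x)) == 1L) {
    return(.test_result(0, length(groups) - 1L, 1, "Kruskal-Wallis"))
  }
  kw <- stats::kruskal.test(groups)
  .test_result(kw$statistic, kw$parameter, kw$p.value, "Kruskal-Wallis")
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Rank-based pairwise z tests following a Kruskal-Wallis comparison. All
#' observations are ranked jointly (midranks for ties); for groups i, j the
#' statistic is
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)}}
#' with the tie correction \eqn{T = \sum (t^3 - t) / (12 (N - 1))} over tie
#' groups of size t. Two-sided p-values; the default reports them
#' unadjusted (the convention of the commonly used implementation), with
#' Bonferroni and Holm adjustments available.
#'
#' @param groups Named list of >= 3 non-empty numeric vectors.
#' @param adjustment `"none"` (default), `"bonferroni"` or `"holm"`.
#' @return Data frame with one row per pair: `group1`, `group2`, `z`,
#'   `p_unadjusted`, `p_value`, `adjustment`.
#' @export
dunn_posthoc <- function(groups, adjustment = c("none", "bonferroni", "holm")) {
  adjustment <- match.arg(adjustment)
  if (length(groups) < 3) stop("Dunn's test needs >= 3 groups")
  if (any(vapply(groups, length, 1L) == 0)) stop("empty group supplied")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, 1L))
  n <- length(x)
  r <- rank(x)
  tie_sizes <- table(x)
  tie_corr <- sum(tie_sizes^3 - tie_sizes) / (12 * (n - 1))
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  pairs <- utils::combn(names(groups), 2)
  z <- apply(pairs, 2, function(pr) {
    sigma <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni[pr[1]] + 1 / ni[pr[2]]))
    if (sigma == 0) 0 else unname((rbar[pr[1]] - rbar[pr[2]]) / sigma)
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_raw <- pmin(p_raw, 1)
  p_adj <- stats::p.adjust(p_raw, method = adjustment)
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p_unadjusted = p_raw, p_value = p_adj, adjustment = adjustment,
             row.names = NULL)
}

#' Spearman rank-correlation matrix of organ weights
#'
#' Symmetric 3x3 matrix of Spearman rank correlations between trunk,
#' aboveground and root weights of the same trees. Because all three organ
#' weights are monotone transforms of DBH (trunk only at fixed height),
#' correlations near 1 are expected; departures quantify the decoupling
#' introduced by height variation. Constant vectors yield NA entries with a
#' warning.
#'
#' @param w_trunk,w_ag,w_root Equal-length per-tree weight vectors, n >= 3.
#' @return 3x3 matrix with dimnames trunk/aboveground/root.
#' @export
spearman_matrix <- function(w_trunk, w_ag, w_root) {
  m <- cbind(trunk = w_trunk, aboveground = w_ag, root = w_root)
  if (nrow(m) < 3) stop("need n >= 3 trees")
  constant <- apply(m, 2, function(v) stats::sd(v) == 0)
  if (any(constant)) {
    warning("constant weight vector(s): ",
            paste(colnames(m)[constant], collapse = ", "),
            "; correlations undefined (NA)")
  }
  suppressWarnings(stats::cor(m, method = "spearman"))
}

#' Gaussian GLM of total tree weight on ecosystem type
#'
#' Fits total per-tree organ weight (trunk + aboveground + root, kg) on
#' ecosystem type with a Gaussian family and identity link, reference level
#' `"degraded"` — so the intercept is the degraded mean total weight and
#' the natural/restored coefficients are mean differences against it.
#'
#' @param weighted Records from [tree_weights()] with an `ecosystem` column;
#'   every level needs >= 2 trees.
#' @param reference Reference ecosystem level.
#' @return A `glm_fit` list: `coefficients` (estimate, std_error, t, p per
#'   term), `reference_level`, `null_deviance` (+ df), `residual_deviance`
#'   (+ df), `aic`, `n`, and the underlying `stats::glm` object as `fit`.
#' @export
glm_total_weight <- function(weighted, reference = "degraded") {
  need <- c("ecosystem", "w_trunk_kg", "w_ag_kg", "w_root_kg")
  stopifnot(all(need %in% names(weighted)))
  d <- data.frame(
    total = weighted$w_trunk_kg + weighted$w_ag_kg + weighted$w_root_kg,
    ecosystem = factor(weighted$ecosystem))
  if (!reference %in% levels(d$ecosystem)) {
    stop("reference level '", reference, "' absent from the data")
  }
  if (any(table(d$ecosystem) < 2)) stop("every ecosystem level needs >= 2 trees")
  d$ecosystem <- stats::relevel(d$ecosystem, ref = reference)
  fit <- stats::glm(total ~ ecosystem, data = d, family = stats::gaussian())
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(
    coefficients = data.frame(
      term = rownames(co), estimate = co[, 1], std_error = co[, 2],
      t = co[, 3], p = co[, 4], row.names = NULL),
    reference_level = reference,
    null_deviance = unname(fit$null.deviance),
    null_df = as.integer(fit$df.null),
    residual_deviance = unname(fit$deviance),
    residual_df = as.integer(fit$df.residual),
    aic = unname(stats::AIC(fit)),
    n = nrow(d), fit = fit), class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("Gaussian GLM: total organ weight ~ ecosystem (reference: %s), n = %d\n",
              x$reference_level, x$n))
  print(x$coefficients, row.names = FALSE, digits = 5)
  cat(sprintf("Null deviance: %.0f on %d df; residual deviance: %.0f on %d df; AIC %.2f\n",
              x$null_deviance, x$null_df, x$residual_deviance, x$residual_df,
              x$aic))
  invisible(x)
}
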