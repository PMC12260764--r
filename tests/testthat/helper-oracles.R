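# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use different code paths (explicit loops, compass
# bearings, textbook formulas) from the package internals.

# A scene with uniformly scattered trees and arbitrary marks.
random_scene <- function(n, extent = c(60, 40), seed = 1) {
  set.seed(seed)
  trees <- data.frame(
    x_m = runif(n, 0, extent[1]), y_m = runif(n, 0, extent[2]),
    dbh_cm = runif(n, 6, 40), height_m = runif(n, 2, 15))
  structure(list(extent = extent, trees = trees), class = "stand_scene")
}

# Compass bearing in degrees (0 = N, 90 = E), then sector classification
# with the N/S-inclusive diagonal convention.
oracle_quadrant <- function(dx, dy) {
  if (dx == 0 && dy == 0) return("N")
  b <- (atan2(dx, dy) * 180 / pi) %% 360
  if (b <= 45 || b >= 315) "N"
  else if (b < 135) "E"
  else if (b <= 225) "S"
  else "W"
}

# Exhaustive nearest-tree scan per point and quadrant.
pcqm_oracle <- function(scene, design, origin) {
  out <- list()
  for (i in seq_len(design$n_points)) {
    p <- c(origin[1] + (i - 1) * design$point_spacing, origin[2])
    best <- list(N = NULL, E = NULL, S = NULL, W = NULL)
    for (t in seq_len(nrow(scene$trees))) {
      dx <- scene$trees$x_m[t] - p[1]
      dy <- scene$trees$y_m[t] - p[2]
      d <- sqrt(dx^2 + dy^2)
      if (d > design$search_radius) next
      q <- oracle_quadrant(dx, dy)
      b <- best[[q]]
      if (is.null(b) || d < b$d ||
          (d == b$d && (dx + p[1] < b$x ||
                        (dx + p[1] == b$x && dy + p[2] < b$y)))) {
        best[[q]] <- list(d = d, x = dx + p[1], y = dy + p[2], tree = t)
      }
    }
    for (q in c("N", "E", "S", "W")) {
      if (!is.null(best[[q]])) {
        out[[length(out) + 1L]] <- data.frame(
          point = i, quadrant = q, distance_m = best[[q]]$d,
          tree = best[[q]]$tree)
      }
    }
  }
  do.call(rbind, out)
}

# Textbook tie-corrected Kruskal-Wallis H.
kw_oracle <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) * sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Dunn pairwise z statistics recomputed from first principles.
dunn_oracle <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, 1L))
  n <- length(x)
  r <- rank(x)
  ties <- table(x)
  tc <- sum(ties^3 - ties) / (12 * (n - 1))
  nm <- names(groups)
  out <- NULL
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i >= j) next
    ri <- mean(r[g == nm[i]]); rj <- mean(r[g == nm[j]])
    ni <- sum(g == nm[i]); nj <- sum(g == nm[j])
    z <- (ri - rj) / sqrt((n * (n + 1) / 12 - tc) * (1 / ni + 1 / nj))
    out <- rbind(out, data.frame(group1 = nm[i], group2 = nm[j], z = z))
  }
  out
}

# Minimal hand-built survey object for closed-form estimator checks.
fake_survey <- function(distances, n_vacant = 0, ecosystem = "test",
                        design = transect_design()) {
  nr <- length(distances)
  structure(list(
    design = design, site = "s", ecosystem = ecosystem,
    records = data.frame(
      site = rep("s", nr), ecosystem = rep(ecosystem, nr),
      point = seq_len(nr), quadrant = rep("N", nr),
      distance_m = distances, dbh_cm = rep(10, nr), height_m = rep(5, nr)),
    vacancies = if (n_vacant > 0) {
      data.frame(point = seq_len(n_vacant), quadrant = rep("S", n_vacant))
    } else data.frame(point = integer(0), quadrant = character(0))),
    class = "pcqm_survey")
}
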