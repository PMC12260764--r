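#' Transect design for point-centered quarter sampling
#'
#' The survey design: a line transect subdivided into equally spaced
#' sampling points; at each point a circle of `search_radius` metres is split
#' into four compass quadrants (N, S, E, W) and the nearest tree per
#' quadrant is measured. Defaults follow the field protocol: a 250 m
#' transect, 25 points at 10 m intervals, 10 m search radius, laid 10 m from
#' the shoreline.
#'
#' @param transect_length Transect length, m.
#' @param n_points Number of sampling points.
#' @param point_spacing Spacing between points, m.
#' @param search_radius Quarter truncation radius, m.
#' @param shore_offset Distance from the shoreline, m (metadata only).
#' @return A `transect_design` object.
#' @export
transect_design <- function(transect_length = 250, n_points = 25,
                            point_spacing = 10, search_radius = 10,
                            shore_offset = 10) {
  if (n_points < 1) stop("n_points must be >= 1")
  if (point_spacing <= 0) stop("point_spacing must be > 0")
  if (search_radius <= 0) stop("search_radius must be > 0")
  if ((n_points - 1) * point_spacing > transect_length + 1e-9) {
    stop("(n_points - 1) * point_spacing must not exceed transect_length")
  }
  structure(list(transect_length = transect_length, n_points = n_points,
                 point_spacing = point_spacing, search_radius = search_radius,
                 shore_offset = shore_offset),
            class = "transect_design")
}

QUADRANTS <- c("N", "E", "S", "W")

# Compass quadrant of an offset (dx, dy): four 90-degree sectors centred on
# the axes, boundaries at the 45-degree diagonals. Offsets exactly on a
# diagonal go to the N or S sector; a zero offset is labelled N.
quadrant_of <- function(dx, dy) {
  q <- character(length(dx))
  q[dy >= abs(dx)] <- "N"
  q[-dy >= abs(dx) & dy < abs(dx)] <- "S"
  q[dx > abs(dy)] <- "E"
  q[-dx > abs(dy)] <- "W"
  q[dx == 0 & dy == 0] <- "N"
  q
}

#' Sample a stand scene with the point-centered quarter method
#'
#' Lays the transect along the x axis starting at `transect_origin`, and for
#' every sampling point and compass quadrant records the geometrically
#' nearest tree within the design's search radius. Ties are broken by
#' (distance, x, y, tree index). Quarters with no tree inside the radius are
#' retained as vacancies — the truncated design is kept as-is, never
#' re-sampled. Sampling circles may overlap, so one tree can be recorded at
#' two different points (but never twice at the same point).
#'
#' @param scene A `stand_scene`.
#' @param design A [transect_design()].
#' @param transect_origin `c(x, y)` of the first point, m. If `NULL`, an
#'   origin is drawn uniformly (using `seed`) among positions where the
#'   whole transect fits inside the extent.
#' @param seed Integer; only used to draw a random origin.
#' @param site Site label stored on every record.
#' @param ecosystem Ecosystem label stored on every record.
#' @return A `pcqm_survey`: list with `design`, `site`, `ecosystem`,
#'   `records` (one row per sampled tree: `site`, `ecosystem`, `point`,
#'   `quadrant`, `distance_m`, `dbh_cm`, `height_m`) and `vacancies`
#'   (`point`, `quadrant`).
#' @export
sample_pcqm <- function(scene, design, transect_origin = NULL, seed = NULL,
                        site = "site1", ecosystem = "unknown") {
  stopifnot(inherits(scene, "stand_scene"), inherits(design, "transect_design"))
  span <- (design$n_points - 1) * design$point_spacing
  if (is.null(transect_origin)) {
    if (is.null(seed)) stop("supply transect_origin or a seed to draw one")
    if (span > scene$extent[1]) stop("transect does not fit inside the scene extent")
    transect_origin <- with_seed(seed, c(
      stats::runif(1, 0, scene$extent[1] - span),
      stats::runif(1, 0, scene$extent[2])))
  }
  px <- transect_origin[1] + (seq_len(design$n_points) - 1) * design$point_spacing
  py <- rep(transect_origin[2], design$n_points)
  inside <- px >= 0 & px <= scene$extent[1] & py >= 0 & py <= scene$extent[2]
  if (!all(inside)) stop("transect extends outside the scene extent")

  trees <- scene$trees
  rec <- vector("list", design$n_points * 4L)
  vac <- vector("list", design$n_points * 4L)
  k <- 0L
  for (i in seq_len(design$n_points)) {
    # only trees in the x-window of the circle can be candidates
    cand <- if (nrow(trees) > 0) {
      which(abs(trees$x_m - px[i]) <= design$search_radius)
    } else integer(0)
    if (length(cand) > 0) {
      dx <- trees$x_m[cand] - px[i]
      dy <- trees$y_m[cand] - py[i]
      d <- sqrt(dx^2 + dy^2)
      quad <- quadrant_of(dx, dy)
      ok <- d <= design$search_radius
    }
    for (q in QUADRANTS) {
      k <- k + 1L
      idx <- if (length(cand) > 0) which(ok & quad == q) else integer(0)
      if (length(idx) == 0L) {
        vac[[k]] <- data.frame(point = i, quadrant = q)
      } else {
        j <- idx[order(d[idx], trees$x_m[cand][idx], trees$y_m[cand][idx],
                       cand[idx])][1L]
        jt <- cand[j]
        rec[[k]] <- data.frame(
          site = site, ecosystem = ecosystem, point = i, quadrant = q,
          distance_m = d[j], dbh_cm = trees$dbh_cm[jt],
          height_m = trees$height_m[jt])
      }
    }
  }
  empty_rec <- data.frame(site = character(0), ecosystem = character(0),
                          point = integer(0), quadrant = character(0),
                          distance_m = numeric(0), dbh_cm = numeric(0),
                          height_m = numeric(0))
  records <- do.call(rbind, c(list(empty_rec), rec[!vapply(rec, is.null, TRUE)]))
  vacancies <- do.call(rbind, c(list(data.frame(point = integer(0),
                                                quadrant = character(0))),
                                vac[!vapply(vac, is.null, TRUE)]))
  structure(list(design = design, site = site, ecosystem = ecosystem,
                 records = records, vacancies = vacancies),
            class = "pcqm_survey")
}

#' @export
print.pcqm_survey <- function(x, ...) {
  cat(sprintf("PCQM survey '%s' (%s): %d trees, %d vacant quarters over %d points\n",
              x$site, x$ecosystem, nrow(x$records), nrow(x$vacancies),
              x$design$n_points))
  invisible(x)
}

#' Cottam-Curtis density estimate from a PCQM survey
#'
#' The classical mean-distance estimator: with point-to-tree distances
#' \eqn{d_i} (m) over occupied quarters, density (trees/ha) is
#' \eqn{10^4 / \bar d^2}. The vacancy-corrected variant multiplies by the
#' occupied fraction of quarters, deflating the estimate when the truncated
#' search radius leaves quarters empty.
#'
#' @param survey A `pcqm_survey` (or a list of them pooled together).
#' @param vacancy_corrected Apply the occupied-fraction correction?
#' @return Trees per hectare.
#' @export
estimate_density <- function(survey, vacancy_corrected = FALSE) {
  surveys <- if (inherits(survey, "pcqm_survey")) list(survey) else survey
  d <- unlist(lapply(surveys, function(s) s$records$distance_m))
  n_vac <- sum(vapply(surveys, function(s) nrow(s$vacancies), 1L))
  if (length(d) == 0L) stop("all quarters vacant: density is undefined")
  dens <- 1e4 / mean(d)^2
  if (vacancy_corrected) dens <- dens * length(d) / (length(d) + n_vac)
  dens
}

#' Stand basal area per hectare
#'
#' Per-tree basal area is \eqn{\pi (DBH/200)^2} m^2 (DBH in cm); the stand
#' value is the density times the mean per-tree basal area.
#'
#' @param records Data frame with a `dbh_cm` column (all > 0).
#' @param density Trees per hectare (>= 0).
#' @return Basal area, m^2/ha.
#' @export
basal_area <- function(records, density) {
  if (NROW(records) == 0L) stop("no records: basal area is undefined")
  if (any(records$dbh_cm <= 0)) stop("all dbh_cm must be > 0")
  if (density < 0) stop("density must be >= 0")
  density * mean(pi * (records$dbh_cm / 200)^2)
}

DBH_CLASS_LABELS <- c("> 5-10", "> 10-20", "> 20-30", "> 30-40", "> 40")
DBH_CLASS_BREAKS <- c(5, 10, 20, 30, 40, Inf)

#' Assign diameter classes
#'
#' Classes are upper-inclusive half-open intervals (5,10], (10,20], (20,30],
#' (30,40], (40, Inf) cm, labelled `"> 5-10"` etc. A DBH of exactly 10 cm
#' falls in the lower class. Trees at or below 5 cm are below the
#' classification: with `strict = TRUE` (default) they raise an error naming
#' the offending indices; otherwise they yield `NA` with a warning.
#'
#' @param dbh_cm Numeric vector of DBH values, cm.
#' @param strict Error (default) or warn-and-NA on dbh <= 5.
#' @return Factor with the five class labels.
#' @export
assign_dbh_class <- function(dbh_cm, strict = TRUE) {
  below <- which(dbh_cm <= 5)
  if (length(below) > 0) {
    msg <- paste0("dbh <= 5 cm is below the diameter classification (indices ",
                  paste(utils::head(below, 10), collapse = ", "), ")")
    if (strict) stop(msg) else warning(msg)
  }
  cut(dbh_cm, breaks = DBH_CLASS_BREAKS, labels = DBH_CLASS_LABELS,
      right = TRUE)
}

#' Stand structure summary across surveys
#'
#' Dendrometric summary table in the survey-report layout: per ecosystem the
#' tree count, pooled Cottam-Curtis density, stand basal area, and per
#' diameter class the class density (overall density times the class share
#' of records — a documented decomposition choice, since plotless per-class
#' estimators vary), DBH range and height range.
#'
#' @param surveys List of `pcqm_survey` objects (possibly mixed ecosystems).
#' @param vacancy_corrected Passed to [estimate_density()].
#' @return Data frame, one row per (ecosystem, DBH class).
#' @export
structure_table <- function(surveys, vacancy_corrected = FALSE) {
  if (inherits(surveys, "pcqm_survey")) surveys <- list(surveys)
  eco <- vapply(surveys, function(s) s$ecosystem, "")
  out <- lapply(unique(eco), function(e) {
    grp <- surveys[eco == e]
    recs <- do.call(rbind, lapply(grp, function(s) s$records))
    dens <- estimate_density(grp, vacancy_corrected)
    ba <- basal_area(recs, dens)
    cl <- assign_dbh_class(recs$dbh_cm, strict = FALSE)
    per_class <- lapply(levels(cl)[tabulate(cl, nlevels(cl)) > 0], function(lev) {
      sub <- recs[which(cl == lev), ]
      data.frame(ecosystem = e, n_trees = nrow(sub), dbh_class = lev,
                 density_ha = dens * nrow(sub) / nrow(recs),
                 basal_area_m2_ha = ba,
                 dbh_min = min(sub$dbh_cm), dbh_max = max(sub$dbh_cm),
                 height_min = min(sub$height_m), height_max = max(sub$height_m),
                 mean_height_m = mean(sub$height_m))
    })
    do.call(rbind, per_class)
  })
  do.call(rbind, out)
}
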