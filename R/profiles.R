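#' Define an ecosystem profile for stand simulation
#'
#' An ecosystem profile describes one mangrove forest condition as a
#' marked point process: a homogeneous stem intensity (trees/ha), a mixture
#' over diameter-at-breast-height (DBH) classes, a within-class DBH law, a
#' per-class height range, and a monotone height-from-DBH model
#' (linear in log DBH with Gaussian noise, truncated to the class height
#' range and to a 0.1 m floor).
#'
#' @param name Ecosystem label, one of `"natural"`, `"degraded"`, `"restored"`.
#' @param stem_intensity Expected stems per hectare (> 0).
#' @param classes Data frame with one row per DBH class and columns
#'   `dbh_lo`, `dbh_hi` (class support bounds, cm), `prop` (mixing
#'   proportion, must sum to 1), `height_lo`, `height_hi` (height support, m).
#' @param dbh_within_class `"uniform"` (default) or `"lognormal"`
#'   (lognormal truncated to the class bounds).
#' @param height_model Named numeric vector `c(intercept, slope, sd)` of the
#'   mean-height map `H = intercept + slope * log(D)` in metres; `sd` is the
#'   Gaussian noise standard deviation before truncation.
#' @param disturbance_tag Free-text metadata; never used in computation.
#'
#' @return An object of class `ecosystem_profile`.
#' @export
ecosystem_profile <- function(name, stem_intensity, classes,
                              dbh_within_class = c("uniform", "lognormal"),
                              height_model = c(intercept = 0, slope = 3, sd = 1),
                              disturbance_tag = "") {
  dbh_within_class <- match.arg(dbh_within_class)
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(stem_intensity) || length(stem_intensity) != 1L ||
      !is.finite(stem_intensity) || stem_intensity <= 0) {
    stop("stem_intensity must be a single positive number (trees/ha)")
  }
  req <- c("dbh_lo", "dbh_hi", "prop", "height_lo", "height_hi")
  if (!is.data.frame(classes) || !all(req %in% names(classes))) {
    stop("classes must be a data.frame with columns ",
         paste(req, collapse = ", "))
  }
  if (abs(sum(classes$prop) - 1) > 1e-9) {
    stop("class mixing proportions must sum to 1 (got ",
         format(sum(classes$prop)), ")")
  }
  if (any(classes$prop < 0)) stop("mixing proportions must be non-negative")
  if (any(classes$dbh_lo <= 0) || any(classes$dbh_hi <= classes$dbh_lo)) {
    stop("each class needs 0 < dbh_lo < dbh_hi")
  }
  if (any(classes$height_lo <= 0) || any(classes$height_hi < classes$height_lo)) {
    stop("each class needs 0 < height_lo <= height_hi")
  }
  hm <- height_model
  if (!all(c("intercept", "slope", "sd") %in% names(hm)) || hm[["sd"]] < 0) {
    stop("height_model must be c(intercept=, slope=, sd=) with sd >= 0")
  }
  structure(
    list(name = name, stem_intensity = stem_intensity,
         classes = classes, dbh_within_class = dbh_within_class,
         height_model = hm, disturbance_tag = disturbance_tag),
    class = "ecosystem_profile")
}

#' @export
print.ecosystem_profile <- function(x, ...) {
  cat(sprintf("Ecosystem profile '%s': %.2f stems/ha, %d DBH class(es), %s within-class DBH\n",
              x$name, x$stem_intensity, nrow(x$classes), x$dbh_within_class))
  print(x$classes, row.names = FALSE)
  invisible(x)
}

# Least-squares fit of mean height on log(DBH) through the class midpoints;
# slope floored at 0 so the map stays monotone non-decreasing.
.fit_height_model <- function(classes, sd = 1) {
  ld <- log((classes$dbh_lo + classes$dbh_hi) / 2)
  hm <- (classes$height_lo + classes$height_hi) / 2
  if (nrow(classes) == 1L) {
    b <- 0
    a <- hm
  } else {
    b <- max(0, stats::cov(ld, hm) / stats::var(ld))
    a <- mean(hm) - b * mean(ld)
  }
  c(intercept = unname(a), slope = unname(b), sd = sd)
}

#' Study-calibrated ecosystem profiles
#'
#' Returns the three ecosystem profiles (natural, degraded, restored)
#' calibrated to the study's dendrometric survey: per-class estimated
#' densities give the stem intensity (their sum) and the mixing proportions,
#' and the observed per-class DBH and height ranges bound the generated
#' marks. Natural stands carry four diameter classes up to the > 30-40 cm
#' class (thicker trunks); degraded and restored stands only the > 5-10 and
#' > 10-20 cm classes, with restored heights skewed taller.
#'
#' @param height_sd Gaussian noise standard deviation (m) of the
#'   height-from-DBH model before truncation to the class height range.
#' @return Named list of three `ecosystem_profile` objects.
#' @export
study_profiles <- function(height_sd = 1) {
  cls <- function(lo, hi, dens, dlo, dhi, hlo, hhi) {
    data.frame(class_lo = lo, class_hi = hi, density = dens,
               dbh_lo = dlo, dbh_hi = dhi, height_lo = hlo, height_hi = hhi)
  }
  natural <- rbind(
    cls(5, 10,   84.20,  8.66,  9.07,  7.28, 11.43),
    cls(10, 20, 1133.55, 14.92, 19.33,  7.18, 12.50),
    cls(20, 30, 1152.50, 22.71, 25.56,  7.40, 12.49),
    cls(30, 40,  143.64, 32.44, 32.72,  8.00, 10.66))
  degraded <- rbind(
    cls(5, 10,  1414.68,  7.83,  8.47,  5.73, 11.44),
    cls(10, 20, 1232.93, 12.47, 14.31,  6.03, 11.46))
  restored <- rbind(
    cls(5, 10,  4552.36,  7.72,  9.42,  6.81,  9.87),
    cls(10, 20, 3423.70, 10.63, 13.63, 11.07, 12.56))
  build <- function(name, tab, tag) {
    tab$prop <- tab$density / sum(tab$density)
    ecosystem_profile(
      name = name, stem_intensity = sum(tab$density), classes = tab,
      dbh_within_class = "uniform",
      height_model = .fit_height_model(tab, sd = height_sd),
      disturbance_tag = tag)
  }
  list(
    natural  = build("natural",  natural,  "low disturbance; mature secondary forest"),
    degraded = build("degraded", degraded, "high anthropogenic disturbance"),
    restored = build("restored", restored, "juvenile replanted forest; < 15 years"))
}
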