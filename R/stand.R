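#' @title Spatial stand simulation
#' @name stand
#' @description Generate spatially explicit single-species stands whose
#'   density, DBH and height distributions follow an ecosystem profile, so
#'   the PCQM survey and allometric stages can be tested against known truth.
NULL

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so simulation calls never perturb each other.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("a single finite integer seed is required")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Per-site stream: fixed additive offsets from one master seed, so adding a
# site never reshuffles the draws of earlier sites. Kept below 2^31.
site_seed <- function(master_seed, site_index) {
  as.integer((as.numeric(master_seed) * 131L + site_index * 7L) %% 2147483647)
}

# Exact truncated-normal draws by inverse-CDF; degenerate windows clamp.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(numeric(0))
  if (all(sd == 0)) return(pmin(pmax(mean, lo), hi))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  x <- stats::qnorm(u, mean, sd)
  pmin(pmax(x, lo), hi)
}

.new_scene <- function(extent, trees) {
  structure(list(extent = extent, trees = trees), class = "stand_scene")
}

#' Generate a synthetic stand scene
#'
#' Tree locations follow a homogeneous Poisson point process at the
#' profile's stem intensity over a rectangular extent; DBH is drawn from the
#' profile's class mixture and within-class law; height from the profile's
#' monotone height-from-DBH model, truncated to the class height range and
#' floored at 0.1 m. The same (profile, extent, seed) always yields an
#' identical scene.
#'
#' @param profile An [ecosystem_profile()].
#' @param extent Numeric `c(width, depth)` of the rectangle, metres.
#' @param seed Integer seed (required; generation is fully reproducible).
#' @param process `"poisson"` (homogeneous, default) or `"thomas"` — a
#'   Thomas cluster process extension for estimator-robustness experiments.
#' @param cluster_intensity Parents per hectare (Thomas process only).
#' @param cluster_sd Offspring dispersal standard deviation, m (Thomas only).
#'
#' @return A `stand_scene`: list with `extent` and a `trees` data frame
#'   (`x_m`, `y_m`, `dbh_cm`, `height_m`).
#' @export
generate_stand <- function(profile, extent, seed,
                           process = c("poisson", "thomas"),
                           cluster_intensity = 25, cluster_sd = 5) {
  process <- match.arg(process)
  if (!inherits(profile, "ecosystem_profile")) stop("profile must be an ecosystem_profile")
  if (length(extent) != 2L || any(!is.finite(extent)) || any(extent <= 0)) {
    stop("extent must be c(width, depth) with positive area")
  }
  if (missing(seed)) stop("seed must be supplied")
  area_ha <- prod(extent) / 1e4
  with_seed(seed, {
    if (process == "poisson") {
      n <- stats::rpois(1L, profile$stem_intensity * area_ha)
      x <- stats::runif(n, 0, extent[1])
      y <- stats::runif(n, 0, extent[2])
    } else {
      n_par <- stats::rpois(1L, cluster_intensity * area_ha)
      px <- stats::runif(n_par, 0, extent[1])
      py <- stats::runif(n_par, 0, extent[2])
      mu <- profile$stem_intensity / cluster_intensity
      n_off <- stats::rpois(n_par, mu)
      x <- stats::rnorm(sum(n_off), rep(px, n_off), cluster_sd)
      y <- stats::rnorm(sum(n_off), rep(py, n_off), cluster_sd)
      keep <- x >= 0 & x <= extent[1] & y >= 0 & y <= extent[2]
      x <- x[keep]; y <- y[keep]
      n <- length(x)
    }
    if (n == 0L) {
      .new_scene(extent, data.frame(x_m = numeric(0), y_m = numeric(0),
                                    dbh_cm = numeric(0), height_m = numeric(0)))
    } else {
      cls <- profile$classes
      ci <- sample.int(nrow(cls), n, replace = TRUE, prob = cls$prop)
      dbh <- draw_dbh(n, cls, ci, profile$dbh_within_class)
      hm <- profile$height_model
      mu_h <- hm[["intercept"]] + hm[["slope"]] * log(dbh)
      h <- rtruncnorm(n, mu_h, hm[["sd"]],
                      lo = pmax(cls$height_lo[ci], 0.1), hi = cls$height_hi[ci])
      .new_scene(extent, data.frame(x_m = x, y_m = y, dbh_cm = dbh, height_m = h))
    }
  })
}

draw_dbh <- function(n, cls, ci, law) {
  lo <- cls$dbh_lo[ci]; hi <- cls$dbh_hi[ci]
  if (law == "uniform") return(stats::runif(n, lo, hi))
  # lognormal centred on the class midpoint, truncated to the class bounds
  mu <- log((lo + hi) / 2)
  sdl <- (log(hi) - log(lo)) / 4
  plo <- stats::plnorm(lo, mu, sdl)
  phi <- stats::plnorm(hi, mu, sdl)
  pmin(pmax(stats::qlnorm(stats::runif(n, plo, phi), mu, sdl), lo), hi)
}

#' @export
print.stand_scene <- function(x, ...) {
  cat(sprintf("Stand scene %.0f x %.0f m, %d trees\n",
              x$extent[1], x$extent[2], nrow(x$trees)))
  invisible(x)
}

#' Write / read a stand scene as delimited text
#'
#' Plain comma-separated serialization with header
#' `x_m,y_m,dbh_cm,height_m`; the extent is carried on a `# extent:` comment
#' line so a scene round-trips exactly at full double precision.
#'
#' @param scene A `stand_scene`.
#' @param path File path.
#' @return `read_scene` returns the reconstructed `stand_scene`;
#'   `write_scene` returns `path` invisibly.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "stand_scene"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# extent: %.17g %.17g", scene$extent[1], scene$extent[2]), con)
  writeLines("x_m,y_m,dbh_cm,height_m", con)
  if (nrow(scene$trees) > 0) {
    writeLines(do.call(sprintf, c(list("%.17g,%.17g,%.17g,%.17g"),
                                  unname(scene$trees))), con)
  }
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  first <- readLines(path, n = 1L)
  ext <- as.numeric(strsplit(sub("^# extent: ", "", first), " ")[[1]])
  trees <- utils::read.csv(path, comment.char = "#",
                           colClasses = rep("numeric", 4))
  if (!identical(names(trees), c("x_m", "y_m", "dbh_cm", "height_m"))) {
    stop("scene file header must be x_m,y_m,dbh_cm,height_m")
  }
  .new_scene(ext, trees)
}
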