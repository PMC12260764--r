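#' Write / read survey record tables
#'
#' Survey tables are plain comma-separated text with header
#' `site,ecosystem,point,quadrant,distance_m,dbh_cm,height_m`, one row per
#' sampled tree; vacancies travel in a sidecar table
#' (`site,ecosystem,point,quadrant`). Numeric columns are written at full
#' double precision so a dataset round-trips exactly.
#'
#' @param records Survey record data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survey_table <- function(records, path) {
  out <- records
  for (col in c("distance_m", "dbh_cm", "height_m")) {
    if (col %in% names(out)) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate an external survey table
#'
#' Ingests a delimited per-tree table — e.g. a deposited replication file —
#' through a declarative column mapping, then validates every row against
#' the record invariants: distance within the search radius, positive DBH
#' and height, quadrant one of N/S/E/W, point index within the design.
#' Invalid rows are rejected individually and itemized by row number; the
#' read/kept/dropped counts are attached and reported.
#'
#' @param path Delimited text file with a header row.
#' @param column_mapping Named character vector mapping the canonical names
#'   (`site`, `ecosystem`, `point`, `quadrant`, `distance_m`, `dbh_cm`,
#'   `height_m`) to the file's actual column headers. Defaults to the
#'   identity mapping.
#' @param design A [transect_design()] supplying the search radius and
#'   point range used in validation.
#' @param sep Field separator (default comma).
#' @return Data frame of validated records, with attributes `n_read`,
#'   `n_kept`, `n_dropped` and `rejections` (row-numbered reasons).
#' @export
read_survey_table <- function(path, column_mapping = NULL,
                              design = transect_design(), sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  canonical <- c("site", "ecosystem", "point", "quadrant",
                 "distance_m", "dbh_cm", "height_m")
  if (is.null(column_mapping)) {
    column_mapping <- stats::setNames(canonical, canonical)
  }
  missing_map <- setdiff(canonical, names(column_mapping))
  if (length(missing_map) > 0) {
    stop("column_mapping lacks entries for: ", paste(missing_map, collapse = ", "))
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  absent <- setdiff(unname(column_mapping[canonical]), names(raw))
  if (length(absent) > 0) {
    stop("mapped column(s) absent from file: ", paste(absent, collapse = ", "))
  }
  d <- stats::setNames(raw[, unname(column_mapping[canonical])], canonical)
  d$point <- suppressWarnings(as.integer(d$point))
  for (col in c("distance_m", "dbh_cm", "height_m")) {
    d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  }
  reasons <- character(nrow(d))
  flag <- function(bad, why) {
    reasons[bad & reasons == ""] <<- why
  }
  flag(is.na(d$point) | d$point < 1 | d$point > design$n_points,
       sprintf("point index outside 1..%d", design$n_points))
  flag(!d$quadrant %in% QUADRANTS, "quadrant not one of N/S/E/W")
  flag(is.na(d$distance_m) | d$distance_m < 0 |
         d$distance_m > design$search_radius,
       sprintf("distance outside [0, %g] m search radius", design$search_radius))
  flag(is.na(d$dbh_cm) | d$dbh_cm <= 0, "non-positive or unparseable dbh_cm")
  flag(is.na(d$height_m) | d$height_m <= 0, "non-positive or unparseable height_m")
  dup <- duplicated(d[, c("site", "point", "quadrant")])
  flag(dup, "duplicate (site, point, quadrant) quarter")
  keep <- reasons == ""
  rejections <- data.frame(row = which(!keep), reason = reasons[!keep])
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_read") <- nrow(d)
  attr(out, "n_kept") <- nrow(out)
  attr(out, "n_dropped") <- nrow(rejections)
  attr(out, "rejections") <- rejections
  message(sprintf("read_survey_table: %d rows read, %d kept, %d dropped",
                  nrow(d), nrow(out), nrow(rejections)))
  if (nrow(rejections) > 0) {
    for (i in seq_len(min(nrow(rejections), 20))) {
      message(sprintf("  row %d rejected: %s",
                      rejections$row[i], rejections$reason[i]))
    }
  }
  out
}

#' Pipeline configuration
#'
#' Bundles every knob of the simulate -> survey -> weigh -> stats -> report
#' pipeline: the master seed, the ecosystem profiles, the transect design,
#' the allometric parameters, the trunk exponent grouping, the per-hectare
#' pooling mode, the Dunn adjustment, and (for external data) the input
#' table and its column mapping.
#'
#' @param seed Master integer seed; per-site streams derive from it by
#'   fixed offsets.
#' @param profiles Named list of [ecosystem_profile()]s.
#' @param design A [transect_design()].
#' @param params An [allometric_params()].
#' @param n_sites Sites simulated per ecosystem.
#' @param extent Scene extent `c(width, depth)` in m; must fit the transect.
#' @param trunk_grouping Trunk exponent grouping (see [trunk_weight()]).
#' @param pooling Per-hectare pooling, `"pooled"` or `"per_site"`.
#' @param dunn_adjustment `"none"`, `"bonferroni"` or `"holm"`.
#' @param input `"synthetic"` (default) or `"external"`.
#' @param external_path,column_mapping External table location and mapping,
#'   used when `input = "external"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, profiles = study_profiles(),
                            design = transect_design(),
                            params = allometric_params(),
                            n_sites = 3L, extent = c(270, 60),
                            trunk_grouping = c("grouped", "ungrouped"),
                            pooling = c("pooled", "per_site"),
                            dunn_adjustment = c("none", "bonferroni", "holm"),
                            input = c("synthetic", "external"),
                            external_path = NULL, column_mapping = NULL) {
  trunk_grouping <- match.arg(trunk_grouping)
  pooling <- match.arg(pooling)
  dunn_adjustment <- match.arg(dunn_adjustment)
  input <- match.arg(input)
  if (input == "synthetic") {
    stopifnot(length(profiles) >= 1,
              all(vapply(profiles, inherits, TRUE, "ecosystem_profile")))
    if ((design$n_points - 1) * design$point_spacing > extent[1]) {
      stop("extent too narrow for the transect design")
    }
  } else if (is.null(external_path)) {
    stop("external input mode needs external_path")
  }
  structure(list(seed = as.integer(seed), profiles = profiles, design = design,
                 params = params, n_sites = as.integer(n_sites),
                 extent = extent, trunk_grouping = trunk_grouping,
                 pooling = pooling, dunn_adjustment = dunn_adjustment,
                 input = input, external_path = external_path,
                 column_mapping = column_mapping),
            class = "pipeline_config")
}
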