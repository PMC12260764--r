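#' Run the full field-to-figures pipeline
#'
#' Orchestrates simulate -> survey -> weigh -> stats -> report. In
#' synthetic mode it generates `n_sites` stand scenes per ecosystem profile
#' (per-site seeds derived from the master seed by fixed offsets), samples
#' each with the PCQM transect, attaches organ weights and diameter
#' classes, and produces the stand-structure table, the class-weight table
#' (mean +/- SE), the pooled and per-site per-hectare organ totals, and the
#' inferential battery (Shapiro-Wilk on log10 weights, Kruskal-Wallis and
#' Dunn pairwise comparisons per organ, Spearman organ matrices per
#' ecosystem, Gaussian GLM of total weight on ecosystem). In external mode
#' the survey stage is replaced by [read_survey_table()] ingestion. Output
#' is deterministic given the config.
#'
#' @param config A [pipeline_config()].
#' @return A `report_bundle` list: `header` (the decisions in force),
#'   `records` (weighted per-tree table), `structure`, `class_weights`,
#'   `hectare` and `hectare_per_site`, `stats` (nested test results),
#'   `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "simulate"
  bundle <- tryCatch({
    if (config$input == "synthetic") {
      surveys <- list()
      si <- 0L
      for (eco in names(config$profiles)) {
        for (s in seq_len(config$n_sites)) {
          si <- si + 1L
          stage <- sprintf("simulate/survey (%s site %d)", eco, s)
          scene <- generate_stand(config$profiles[[eco]], config$extent,
                                  seed = site_seed(config$seed, si))
          surveys[[si]] <- sample_pcqm(
            scene, config$design, seed = site_seed(config$seed, si) + 1L,
            site = sprintf("%s_%d", eco, s), ecosystem = eco)
        }
      }
      records <- do.call(rbind, lapply(surveys, function(s) s$records))
      stage <- "structure"
      structure_tab <- structure_table(surveys)
    } else {
      stage <- "ingest"
      records <- read_survey_table(config$external_path,
                                   config$column_mapping, config$design)
      surveys <- NULL
      structure_tab <- NULL
    }
    stage <- "weigh"
    weighted <- tree_weights(records, config$params, config$trunk_grouping)
    class_tab <- summarize_by_class(weighted)
    n_sites_vec <- tapply(weighted$site, weighted$ecosystem,
                          function(s) length(unique(s)))
    hectare <- hectare_totals(weighted, config$design, "pooled",
                              n_sites = n_sites_vec)
    hectare_site <- hectare_totals(weighted, config$design, "per_site")
    stage <- "stats"
    stats_out <- run_stats(weighted, config$dunn_adjustment)
    header <- c(
      sprintf("seed: %d", config$seed),
      sprintf("input: %s", config$input),
      sprintf("trunk equation exponent grouping: %s", config$trunk_grouping),
      sprintf("per-hectare pooling: %s (per-site table also emitted)", config$pooling),
      sprintf("Dunn adjustment: %s", config$dunn_adjustment),
      "note: sampling-circle overlap is ignored in the per-hectare area term")
    structure(list(header = header, records = weighted,
                   structure = structure_tab, class_weights = class_tab,
                   hectare = hectare, hectare_per_site = hectare_site,
                   stats = stats_out, config = config),
              class = "report_bundle")
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  bundle
}

# Inferential battery over the weighted per-tree records.
run_stats <- function(weighted, dunn_adjustment = "none") {
  organs <- c(trunk = "w_trunk_kg", aboveground = "w_ag_kg", root = "w_root_kg")
  by_org <- lapply(organs, function(col) split(weighted[[col]], weighted$ecosystem))
  shapiro <- lapply(organs, function(col)
    shapiro_wilk(log10_transform(weighted[[col]])))
  kw <- lapply(by_org, kruskal_wallis)
  dunn <- lapply(by_org, dunn_posthoc, adjustment = dunn_adjustment)
  spearman <- lapply(split(weighted, weighted$ecosystem), function(d)
    spearman_matrix(d$w_trunk_kg, d$w_ag_kg, d$w_root_kg))
  glm_fit <- if (length(unique(weighted$ecosystem)) >= 2 &&
                 "degraded" %in% weighted$ecosystem) {
    glm_total_weight(weighted, reference = "degraded")
  } else NULL
  list(shapiro = shapiro, kruskal = kw, dunn = dunn,
       spearman = spearman, glm = glm_fit)
}

#' Write a report bundle to a directory
#'
#' Emits the machine tables (full precision, comma-separated) and a
#' human-readable `report.txt` whose numbers are printed at 2 decimals, the
#' reporting precision of the tables it mirrors. The header echoes every
#' methodological decision in force so outputs are self-describing.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  full <- function(d) {
    for (col in names(d)) if (is.numeric(d[[col]]) && !is.integer(d[[col]]))
      d[[col]] <- sprintf("%.17g", d[[col]])
    d
  }
  utils::write.csv(full(bundle$records), file.path(dir, "tree_weights.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(bundle$structure)) {
    utils::write.csv(full(bundle$structure), file.path(dir, "stand_structure.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(full(bundle$class_weights), file.path(dir, "class_weights.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(full(bundle$hectare), file.path(dir, "hectare_totals.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(full(bundle$hectare_per_site),
                   file.path(dir, "hectare_totals_per_site.csv"),
                   row.names = FALSE, quote = FALSE)
  stats_rows <- report_stats_table(bundle$stats)
  utils::write.csv(full(stats_rows), file.path(dir, "stats_results.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(render_report(bundle), file.path(dir, "report.txt"))
  invisible(dir)
}

# Long-format table of every test result in the bundle.
report_stats_table <- function(st) {
  rows <- list()
  for (org in names(st$kruskal)) {
    sh <- st$shapiro[[org]]
    kw <- st$kruskal[[org]]
    rows[[length(rows) + 1L]] <- data.frame(
      analysis = c("shapiro_wilk_log10", "kruskal_wallis"), organ = org,
      ecosystem_pair = NA_character_,
      statistic = c(sh$statistic, kw$statistic), df = c(sh$df, kw$df),
      p = c(sh$p_value, kw$p_value), adjustment = c("none", "none"))
    dn <- st$dunn[[org]]
    rows[[length(rows) + 1L]] <- data.frame(
      analysis = "dunn", organ = org,
      ecosystem_pair = paste(dn$group1, dn$group2, sep = "-"),
      statistic = dn$z, df = NA_real_, p = dn$p_value,
      adjustment = dn$adjustment)
  }
  if (!is.null(st$glm)) {
    co <- st$glm$coefficients
    rows[[length(rows) + 1L]] <- data.frame(
      analysis = "glm_total_weight", organ = "total",
      ecosystem_pair = co$term, statistic = co$t,
      df = st$glm$residual_df, p = co$p, adjustment = "none")
  }
  do.call(rbind, rows)
}

render_report <- function(bundle) {
  f2 <- function(x) formatC(x, format = "f", digits = 2)
  out <- c("Mangrove stand organ-weight report", "==================================",
           bundle$header, "")
  out <- c(out, sprintf("Trees sampled: %d", nrow(bundle$records)), "")
  out <- c(out, "Per-hectare organ totals (kg/ha, pooled points):")
  h <- bundle$hectare
  out <- c(out, sprintf("  %-9s %-12s %10s", h$ecosystem, h$organ, f2(h$kg_per_ha)), "")
  for (org in names(bundle$stats$kruskal)) {
    kw <- bundle$stats$kruskal[[org]]
    out <- c(out, sprintf(
      "%s weight: Kruskal-Wallis chi-squared = %s, df = %d, p = %.3g",
      org, f2(kw$statistic), kw$df, kw$p_value))
    dn <- bundle$stats$dunn[[org]]
    out <- c(out, sprintf("  Dunn %s vs %s: z = %s, p = %.3g (%s)",
                          dn$group1, dn$group2, f2(dn$z), dn$p_value,
                          dn$adjustment))
  }
  if (!is.null(bundle$stats$glm)) {
    g <- bundle$stats$glm
    out <- c(out, "", sprintf(
      "GLM total weight ~ ecosystem (reference %s), n = %d, AIC = %s:",
      g$reference_level, g$n, f2(g$aic)))
    co <- g$coefficients
    out <- c(out, sprintf("  %-28s est %10s  se %8s  t %7s  p %.3g",
                          co$term, f2(co$estimate), f2(co$std_error),
                          f2(co$t), co$p))
  }
  out
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
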