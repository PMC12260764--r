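test_that("design invariants are enforced", {
  expect_error(transect_design(n_points = 0), "n_points")
  expect_error(transect_design(point_spacing = 0), "point_spacing")
  expect_error(transect_design(search_radius = -1), "search_radius")
  expect_error(transect_design(transect_length = 100, n_points = 25,
                               point_spacing = 10), "exceed")
  expect_silent(transect_design())
})

test_that("an empty scene yields only vacancies", {
  sc <- structure(list(extent = c(300, 50),
                       trees = data.frame(x_m = numeric(0), y_m = numeric(0),
                                          dbh_cm = numeric(0),
                                          height_m = numeric(0))),
                  class = "stand_scene")
  sv <- sample_pcqm(sc, transect_design(), transect_origin = c(10, 25))
  expect_identical(nrow(sv$records), 0L)
  expect_identical(nrow(sv$vacancies), 25L * 4L)
})

test_that("a single tree due north is recorded once, in quadrant N", {
  sc <- structure(list(extent = c(300, 50),
                       trees = data.frame(x_m = 10, y_m = 28, dbh_cm = 15,
                                          height_m = 7)),
                  class = "stand_scene")
  sv <- sample_pcqm(sc, transect_design(), transect_origin = c(10, 25))
  expect_identical(nrow(sv$records), 1L)
  expect_identical(sv$records$point, 1L)
  expect_identical(sv$records$quadrant, "N")
  expect_equal(sv$records$distance_m, 3)
  # records + vacancies tile all quarters
  expect_identical(nrow(sv$records) + nrow(sv$vacancies), 25L * 4L)
})

test_that("a transect outside the extent is rejected", {
  sc <- random_scene(50, extent = c(100, 40), seed = 2)
  expect_error(sample_pcqm(sc, transect_design(), transect_origin = c(10, 20)),
               "outside the scene extent")
})

test_that("nearest-tree selection matches the brute-force oracle", {
  design <- transect_design(transect_length = 40, n_points = 5,
                            point_spacing = 10, search_radius = 10)
  for (s in 1:40) {
    sc <- random_scene(rpois(1, 80) + 1, extent = c(60, 40), seed = s)
    origin <- c(runif(1, 0, 20), runif(1, 5, 35))
    sv <- sample_pcqm(sc, design, transect_origin = origin)
    orc <- pcqm_oracle(sc, design, origin)
    got <- sv$records[order(sv$records$point, sv$records$quadrant), ]
    want <- orc[order(orc$point, orc$quadrant), ]
    expect_identical(nrow(got), nrow(want))
    expect_equal(got$distance_m, want$distance_m, tolerance = 0)
    expect_identical(got$quadrant, want$quadrant)
    expect_identical(got$point, as.integer(want$point))
  }
})

test_that("duplicate quarters never occur within a point", {
  sc <- random_scene(300, extent = c(300, 50), seed = 7)
  sv <- sample_pcqm(sc, transect_design(), transect_origin = c(15, 25))
  expect_false(any(duplicated(sv$records[, c("point", "quadrant")])))
})

test_that("density estimator has its closed forms", {
  expect_equal(estimate_density(fake_survey(rep(5, 8))), 400)
  expect_equal(estimate_density(fake_survey(10)), 100)
  expect_error(estimate_density(fake_survey(numeric(0), n_vacant = 8)),
               "vacant")
  # vacancy correction multiplies by the occupied fraction
  sv <- fake_survey(rep(5, 6), n_vacant = 2)
  expect_equal(estimate_density(sv, vacancy_corrected = TRUE), 400 * 6 / 8)
})

test_that("Cottam-Curtis density recovers a known Poisson intensity", {
  cls <- data.frame(dbh_lo = 5, dbh_hi = 10, prop = 1,
                    height_lo = 2, height_hi = 8)
  prof <- ecosystem_profile("x", 2500, cls)
  design <- transect_design()
  est <- vapply(1:30, function(s) {
    sc <- generate_stand(prof, c(270, 50), seed = 1000 + s)
    estimate_density(sample_pcqm(sc, design, transect_origin = c(10, 25)))
  }, 1)
  expect_lt(abs(mean(est) - 2500) / 2500, 0.10)
})

test_that("density estimate sharpens as the transect grows", {
  cls <- data.frame(dbh_lo = 5, dbh_hi = 10, prop = 1,
                    height_lo = 2, height_hi = 8)
  prof <- ecosystem_profile("x", 2500, cls)
  short <- transect_design(250, 25, 10, 10)
  long <- transect_design(2000, 200, 10, 10)
  rel_err <- function(design, width, seed) {
    sc <- generate_stand(prof, c(width, 40), seed = seed)
    abs(estimate_density(sample_pcqm(sc, design,
                                     transect_origin = c(5, 20))) - 2500) / 2500
  }
  e_short <- vapply(1:12, function(s) rel_err(short, 270, 3000 + s), 1)
  e_long <- vapply(1:12, function(s) rel_err(long, 2010, 4000 + s), 1)
  expect_lt(median(e_long), median(e_short))
})

test_that("basal area has its closed form and invariances", {
  one <- data.frame(dbh_cm = 20)
  expect_equal(basal_area(one, 100), pi * 0.1^2 * 100)
  expect_lt(basal_area(data.frame(dbh_cm = 1e-6), 100), 1e-9)
  expect_error(basal_area(data.frame(dbh_cm = numeric(0)), 100), "no records")
  expect_error(basal_area(data.frame(dbh_cm = c(3, -2)), 100), "> 0")
  set.seed(31)
  recs <- data.frame(dbh_cm = runif(200, 6, 40))
  # independent re-summation
  want <- 350 * sum(pi * (recs$dbh_cm / 200)^2) / nrow(recs)
  expect_equal(basal_area(recs, 350), want, tolerance = 1e-9)
  # linear in density, permutation-invariant
  expect_equal(basal_area(recs, 700), 2 * basal_area(recs, 350))
  perm <- recs[sample(nrow(recs)), , drop = FALSE]
  expect_equal(basal_area(perm, 350), basal_area(recs, 350))
})

test_that("diameter classes partition (5, Inf) with upper-inclusive bounds", {
  expect_identical(as.character(assign_dbh_class(10.0)), "> 5-10")
  expect_identical(as.character(assign_dbh_class(32.72)), "> 30-40")
  expect_identical(as.character(assign_dbh_class(8.66)), "> 5-10")
  expect_identical(as.character(assign_dbh_class(c(20, 20.001, 40, 40.5))),
                   c("> 10-20", "> 20-30", "> 30-40", "> 40"))
  expect_error(assign_dbh_class(5), "below the diameter classification")
  expect_warning(cl <- assign_dbh_class(c(4, 12), strict = FALSE), "below")
  expect_true(is.na(cl[1]) && cl[2] == "> 10-20")
  set.seed(8)
  x <- runif(500, 5 + 1e-9, 100)
  cl <- assign_dbh_class(x)
  expect_false(any(is.na(cl)))   # every dbh maps to exactly one class
})

test_that("structure table aggregates ecosystems and classes coherently", {
  pr <- study_profiles()
  surveys <- lapply(1:2, function(s) {
    sc <- generate_stand(pr$natural, c(270, 60), seed = 50 + s)
    sample_pcqm(sc, transect_design(), transect_origin = c(10, 30),
                site = paste0("n", s), ecosystem = "natural")
  })
  tab <- structure_table(surveys)
  recs <- do.call(rbind, lapply(surveys, function(s) s$records))
  expect_equal(sum(tab$n_trees), nrow(recs))
  # class densities decompose the pooled Cottam-Curtis estimate
  expect_equal(sum(tab$density_ha), estimate_density(surveys))
  expect_true(all(tab$dbh_min > 5))
})
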