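test_that("field generation is deterministic under a fixed seed", {
  a <- generate_field(image_scene_spec(seed = 13))
  b <- generate_field(image_scene_spec(seed = 13))
  expect_identical(a$field$dapi, b$field$dapi)
  expect_identical(a$field$mpo, b$field$mpo)
  expect_identical(a$field$cith3, b$field$cith3)
  expect_identical(a$truth$true_coloc_area_px, b$truth$true_coloc_area_px)
})

test_that("scene without filaments has zero true and measured coloc area", {
  sim <- generate_field(image_scene_spec(seed = 3, n_nets_filaments = 0,
                                         n_primed_neutrophils = 0))
  expect_equal(sim$truth$true_coloc_area_px, 0)
  # Otsu is meaningless on a signal-free Cit-H3 channel (pure noise is not
  # bimodal), so the negative-control analog uses manual cutoffs, as the
  # original workflow did
  q <- quantify_field(sim$field, threshold_config(
    mpo_threshold = 100, cith3_threshold = 100, dapi_threshold = 100))
  expect_equal(q$coloc_area, 0)
})

test_that("noiseless fields are recovered exactly", {
  for (s in c(7, 19, 23)) {
    sim <- generate_field(image_scene_spec(
      seed = s, n_cells = 10, n_neutrophils = 4,
      noise_sigma = 0, psf_sigma_px = 0))
    q <- quantify_field(sim$field)
    expect_equal(q$cell_count, 10)
    expect_equal(q$neutrophil_count, 4)
    expect_equal(q$coloc_area, sim$truth$true_coloc_area_px)
  }
})

test_that("primed neutrophils contribute Cit-H3 but not spurious coloc", {
  sim <- generate_field(image_scene_spec(
    seed = 29, n_nets_filaments = 0, n_primed_neutrophils = 2,
    noise_sigma = 0, psf_sigma_px = 0))
  # nuclear Cit-H3 exists, but MPO is cytoplasmic: intersection stays empty
  expect_gt(sum(sim$truth$cith3_mask), 0)
  expect_equal(sim$truth$true_coloc_area_px, 0)
  expect_equal(quantify_field(sim$field)$coloc_area, 0)
})

test_that("infeasible non-touching placement errors out", {
  expect_error(
    generate_field(image_scene_spec(field_size_px = 80, n_cells = 60,
                                    n_neutrophils = 0,
                                    n_primed_neutrophils = 0, seed = 1)),
    "infeasible placement")
})

test_that("scene spec validates object counts", {
  expect_error(image_scene_spec(n_cells = 3, n_neutrophils = 5), "<=")
  expect_error(image_scene_spec(n_neutrophils = 2, n_primed_neutrophils = 3),
               "<=")
})

test_that("cohort generation is deterministic and matches the group design", {
  a <- generate_cohort(cohort_sim_spec(seed = 99))
  b <- generate_cohort(cohort_sim_spec(seed = 99))
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$measurements, b$measurements)
  expect_equal(nrow(a$cohort), 33)
  expect_equal(as.vector(table(a$cohort$group_label)[c(
    "healthy", "moderate", "severe")]), c(12L, 7L, 14L))
})

test_that("generated cytology is valid and classification-consistent", {
  for (s in c(2, 5, 8)) {
    sim <- generate_cohort(cohort_sim_spec(seed = s))
    co <- sim$cohort
    sums <- co$macrophages + co$lymphocytes + co$neutrophils +
      co$eosinophils + co$mast_cells
    expect_true(all(sums >= 95 & sums <= 105))
    expect_true(all(co[, c("macrophages", "lymphocytes", "neutrophils",
                           "eosinophils", "mast_cells")] >= 0))
    # rule-based classification reproduces the intended groups exactly
    expect_identical(classify_phenotype(co), co$group_label)
  }
})

test_that("a zeroed severity effect yields a null cf DNA comparison", {
  sim <- generate_cohort(cohort_sim_spec(seed = 42, effect_scale = 0))
  g <- split(sim$measurements$cfdna_ug_ml, sim$measurements$group)
  cmp <- suppressWarnings(compare_groups(g))
  expect_gt(cmp$omnibus_p, 0.05)
})

test_that("field images and ground truth serialize to disk", {
  dir <- tempfile()
  sim <- generate_field(image_scene_spec(seed = 4, n_cells = 8,
                                         n_neutrophils = 3))
  write_field_images(sim, dir)
  f <- read_field(file.path(dir, "dapi.pgm"), file.path(dir, "mpo.pgm"),
                  file.path(dir, "cith3.pgm"), subject_id = "S",
                  field_id = "f1")
  # PGM stores rounded integers; quantification still recovers the counts
  q <- quantify_field(f)
  expect_equal(q$cell_count, 8)
  expect_equal(q$neutrophil_count, 3)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$true_cell_count, 8)
})
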