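asth <- read_cohort_csv(cohort_fixture_path("asthmatic"))
healthy <- read_cohort_csv(cohort_fixture_path("healthy"))

test_that("granulocyte cutoffs are strict", {
  # mast cells elevated
  expect_true(is_asthmatic(balf_cytology(60, 34, 1.5, 0, 4.5)))
  # everything at or below the reference cutoffs
  expect_false(is_asthmatic(balf_cytology(63, 33.5, 1.5, 0, 2)))
  # exact boundary values do not qualify
  expect_false(is_asthmatic(balf_cytology(60, 32, 5, 1, 2)))
})

test_that("cytology validation rejects malformed records", {
  expect_error(balf_cytology(120, 0, 0, 0, 0), "\\[0, 100\\]")
  expect_error(balf_cytology(10, 10, 10, 10, 10), "outside \\[95, 105\\]")
  expect_error(balf_cytology(60, NA, 30, 0, 10), "non-numeric")
  # differential on 300 cells rounds to halves; sums in [95,105] accepted
  expect_s3_class(balf_cytology(22, 29, 49, 0, 3), "balf_cytology")
})

test_that("phenotype rules match the printed examples", {
  # severe despite neutrophils <= 20%: labored breathing decides
  sea4 <- horse_record("SEA4", balf_cytology(26.5, 50.5, 14, 0, 9),
                       labored_breathing_at_rest = TRUE,
                       abnormal_lung_auscultation = TRUE)
  expect_identical(classify_phenotype(sea4), "severe")
  # moderate: asthmatic cytology, quiet exam
  mea2 <- horse_record("MEA2", balf_cytology(34.5, 48, 15, 0, 2.5))
  expect_identical(classify_phenotype(mea2), "moderate")
  healthy2 <- horse_record("H2", balf_cytology(47, 48, 4, 0, 1))
  expect_identical(classify_phenotype(healthy2), "healthy")
  # neutrophilia alone above 20% is sufficient
  quiet_high <- horse_record("X", balf_cytology(30, 40, 28, 0, 2))
  expect_identical(classify_phenotype(quiet_high), "severe")
})

test_that("moderate subgrouping splits at 5% (boundary to neu_hi)", {
  lo <- horse_record("lo", balf_cytology(33.5, 60.5, 1.5, 0, 4.5))
  hi <- horse_record("hi", balf_cytology(45.5, 46, 8, 0.5, 0))
  at5 <- horse_record("at5", balf_cytology(50, 42, 5, 0, 3))
  expect_identical(subgroup_moderate(lo), "neu_lo")
  expect_identical(subgroup_moderate(hi), "neu_hi")
  expect_identical(subgroup_moderate(at5), "neu_hi")
  sev <- horse_record("sev", balf_cytology(17, 10, 73, 0, 0),
                      labored_breathing_at_rest = TRUE)
  expect_error(subgroup_moderate(sev), "moderate")
})

test_that("fixtures reproduce the printed cohort structure", {
  expect_equal(nrow(asth), 21)
  expect_equal(nrow(healthy), 12)
  cls <- classify_phenotype(asth)
  expect_equal(sum(cls == "severe"), 14)
  expect_equal(sum(cls == "moderate"), 7)
  # rule-based labels agree with the enrollment labels for every asthmatic
  expect_identical(cls, asth$group_label)
  sub <- subgroup_moderate(asth[cls == "moderate", ])
  expect_equal(as.vector(table(sub)[c("neu_lo", "neu_hi")]), c(3L, 4L))
  # the single missing tracheal-wash entry stays missing
  expect_equal(sum(is.na(asth$tracheal_neut_gt20)), 1)
})

test_that("explicit healthy labels override the cytology rule with a warning", {
  # two healthy controls exceed the 5% neutrophil reference
  rule <- classify_phenotype(healthy)
  expect_equal(sum(rule != "healthy"), 2)
  expect_warning(cls <- classify_cohort(healthy), "enrollment label")
  expect_true(all(cls == "healthy"))
  # without label preference the rule stands
  expect_identical(classify_cohort(healthy, prefer_label = FALSE), rule)
})

test_that("classification is deterministic and order-independent", {
  set.seed(11)
  perm <- sample(nrow(asth))
  cls <- classify_phenotype(asth)
  expect_identical(classify_phenotype(asth[perm, ]), cls[perm])
})

test_that("cohort CSV round-trips and reports parse errors precisely", {
  tmp <- tempfile(fileext = ".csv")
  write_cohort_csv(asth, tmp)
  back <- read_cohort_csv(tmp)
  expect_equal(as.data.frame(back), as.data.frame(asth),
               ignore_attr = TRUE)

  # header-only file: zero records
  empty <- tempfile(fileext = ".csv")
  writeLines(paste(c("subject_id", "group_label", "labored_breathing",
                     "abnormal_auscultation", "mucus_score",
                     "tracheal_neut_gt20", "wcs", "macrophages",
                     "lymphocytes", "neutrophils", "eosinophils",
                     "mast_cells"), collapse = ","), empty)
  expect_equal(nrow(read_cohort_csv(empty)), 0)

  # missing column
  df <- read.csv(tmp)
  df$neutrophils <- NULL
  bad <- tempfile(fileext = ".csv")
  write.csv(df, bad, row.names = FALSE)
  expect_error(read_cohort_csv(bad), "neutrophils")

  # non-numeric cytology names row and column
  df2 <- read.csv(tmp, colClasses = "character")
  df2$eosinophils[3] <- "high"
  write.csv(df2, bad, row.names = FALSE)
  expect_error(read_cohort_csv(bad), "column 'eosinophils', row 3")
})
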