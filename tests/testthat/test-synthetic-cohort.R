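# Synthetic cohort generator: quota marginals, logistic labels, splits.

test_that("quota mode reproduces the published per-category counts exactly", {
  co <- simulate_cohort(cohort_spec(seed = 1))
  expect_equal(nrow(co), 2675)
  tb <- table(co$tongue_body)
  expect_equal(unname(tb[c("medium", "enlarged", "small")]),
               c(1332L, 915L, 428L), ignore_attr = TRUE)
  marg <- table1_marginals()
  for (feat in c("tongue_color", "fur_color", "fur_thickness", "saliva")) {
    cnt <- table(co[[feat]])
    expect_equal(unname(cnt[names(marg[[feat]])]), unname(marg[[feat]]),
                 ignore_attr = TRUE, info = feat)
  }
  expect_equal(sum(co$label == "DM"), 1658)
})

test_that("quota marginals are exact for every seed", {
  for (seed in c(7, 2026)) {
    co <- simulate_cohort(cohort_spec(n_total = 200, n_dm = 80,
                                      seed = seed))
    for (feat in names(table1_marginals())[1:5]) {
      cnt <- table(co[[feat]])
      expect_equal(sum(cnt), 200, info = feat)
    }
    expect_equal(sum(co$label == "DM"), 80)
  }
})

test_that("fur colour 'none' coincides with absent fur", {
  co <- simulate_cohort(cohort_spec(seed = 3))
  expect_true(all(co$fur_color[co$fur_thickness == "no_fur"] == "none"))
  # the 58 surplus none-coloured records sit on thin-fur tongues
  extra <- co$fur_thickness[co$fur_color == "none"]
  expect_equal(sum(extra == "no_fur"), 217)
  expect_true(all(extra %in% c("no_fur", "thin")))
})

test_that("identical spec and seed give byte-identical cohort files", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(simulate_cohort(cohort_spec(seed = 42)), f1)
  write_feature_table(simulate_cohort(cohort_spec(seed = 42)), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("intercept calibration reproduces the base rate exactly under null effects", {
  b0 <- calibrate_intercept(rep(0, 100), 1658 / 2675)
  expect_equal(plogis(b0), 1658 / 2675, tolerance = 1e-6)
  expect_error(calibrate_intercept(rep(1e6, 10), 0.5),
               class = "tonguenet_calibration_error")
})

test_that("null effects give label-independent features at the base rate", {
  # n_total 10, n_dm 5, multinomial labels: repeated simulation centres
  # the DM fraction on 1/2
  fracs <- vapply(1:200, function(s) {
    co <- simulate_cohort(cohort_spec(n_total = 10, n_dm = 5,
                                      effects = effect_model_null(),
                                      sampling = "multinomial", seed = s))
    mean(co$label == "DM")
  }, 0)
  expect_gt(mean(fracs), 0.4)
  expect_lt(mean(fracs), 0.6)
})

test_that("a strong single offset reproduces the analytic logistic gap", {
  # P(DM | thick) - P(DM | thin) from simulation vs the closed form
  eff <- list(fur_thickness = c(thick = 4))
  gaps <- vapply(1:20, function(s) {
    co <- simulate_cohort(cohort_spec(n_total = 4000, n_dm = 2000,
                                      effects = eff,
                                      sampling = "multinomial", seed = s))
    mean(co$label[co$fur_thickness == "thick"] == "DM") -
      mean(co$label[co$fur_thickness == "thin"] == "DM")
  }, 0)
  co <- simulate_cohort(cohort_spec(n_total = 4000, n_dm = 2000, effects = eff,
                                    sampling = "multinomial", seed = 99))
  b0 <- attr(co, "intercept")
  analytic <- plogis(b0 + 4) - plogis(b0)
  expect_equal(mean(gaps), analytic, tolerance = 0.02)
})

test_that("the stratified split reproduces the published 70/30 class counts", {
  co <- simulate_cohort(cohort_spec(seed = 5))
  sp <- split_cohort(co, 0.7, seed = 5)
  expect_equal(sum(sp$train$label == "DM"), 1161)
  expect_equal(sum(sp$train$label == "non_DM"), 712)
  expect_equal(sum(sp$test$label == "DM"), 497)
  expect_equal(sum(sp$test$label == "non_DM"), 305)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(co))
})

test_that("split sizes follow round-half-up per class", {
  even <- mixed_records(20, seed = 1)
  even$label <- rep(c("DM", "non_DM"), 10)
  sp <- split_cohort(even, 0.5, seed = 1)
  expect_equal(unname(table(sp$train$label)), c(5L, 5L), ignore_attr = TRUE)

  skewed <- mixed_records(10, seed = 2)
  skewed$label <- c(rep("DM", 7), rep("non_DM", 3))
  sp <- split_cohort(skewed, 0.7, seed = 1)              # 4.9 -> 5, 2.1 -> 2
  expect_equal(sum(sp$train$label == "DM"), 5)
  expect_equal(sum(sp$train$label == "non_DM"), 2)

  single <- skewed
  single$label <- c(rep("DM", 9), "non_DM")
  expect_error(split_cohort(single, 0.7), class = "tonguenet_data_error")
  expect_error(split_cohort(skewed, 1.2), class = "tonguenet_config_error")
})

test_that("config validation rejects malformed specs", {
  expect_error(cohort_spec(n_dm = 3000), class = "tonguenet_config_error")
  bad <- table1_marginals()
  bad$saliva <- c(normal = 0.5, dry = 0.3, wet = 0.2)
  expect_error(cohort_spec(marginals = bad, sampling = "quota"),
               class = "tonguenet_config_error")
  bad$saliva <- c(normal = 1884.5, dry = 517.5, wet = 273)
  expect_error(cohort_spec(marginals = bad, sampling = "quota"),
               class = "tonguenet_config_error")
})

test_that("optional phase column carries the four published phase sizes", {
  co <- simulate_cohort(cohort_spec(include_phase = TRUE, seed = 8))
  expect_equal(unname(table(co$phase)[paste0("phase", 1:4)]),
               c(530L, 750L, 1062L, 333L), ignore_attr = TRUE)
})
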