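test_that("default treatment grid has 26 unique treatments with the anchor cells", {
  g <- default_treatment_grid()
  expect_equal(nrow(g), 26)
  expect_equal(anyDuplicated(g), 0)
  expect_true(all(g$concentration_uM %in% c(0, 2, 5, 8, 10, 20, 40, 60, 80, 100)))
  expect_true(all(g$exposure_h %in% c(10, 12, 18, 24, 36)))
  anchors <- rbind(c(10, 12), c(100, 10), c(40, 24), c(40, 36),
                   c(60, 24), c(60, 36), c(80, 24))
  for (i in seq_len(nrow(anchors))) {
    expect_true(any(g$concentration_uM == anchors[i, 1] &
                      g$exposure_h == anchors[i, 2]),
                info = paste("missing anchor", anchors[i, 1], anchors[i, 2]))
  }
  expect_true(any(g$concentration_uM == 0))
})

test_that("class probabilities form a simplex for random treatments", {
  withr_seed(7)
  conc <- runif(1000, 0, 100)
  expo <- runif(1000, 0, 48)
  p <- class_probabilities(conc, expo)
  expect_within(p, 0, 1)
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
})

test_that("dose-response defaults reproduce the calibrated response pattern", {
  # low dose: diploid-only region
  low <- expand.grid(C = c(0, 2, 5), t = c(0, 10, 12, 24, 36, 48))
  expect_true(all(class_probabilities(low$C, low$t)[, "diploid"] >= 0.95))
  # high-conversion block
  blk <- expand.grid(C = c(40, 60, 80), t = c(24, 36))
  expect_within(class_probabilities(blk$C, blk$t)[, "tetraploid"], 0.70, 0.92)
  # planted optimum, and it beats the best block treatment
  p_opt <- class_probabilities(33, 18)
  expect_gte(p_opt[, "tetraploid"], 0.93)
  expect_gt(p_opt[, "tetraploid"],
            class_probabilities(60, 36)[, "tetraploid"])
  # extreme dose with a short pulse leaves mostly chimeras
  p_ext <- class_probabilities(100, 10)
  expect_equal(colnames(p_ext)[which.max(p_ext)], "mixoploid")
})

test_that("class_probabilities rejects out-of-bounds treatments", {
  expect_error(class_probabilities(-1, 10), "concentration")
  expect_error(class_probabilities(101, 10), "concentration")
  expect_error(class_probabilities(50, 49), "exposure")
  expect_error(class_probabilities(c(1, 2), 10), "length")
})

test_that("simulate_experiment is seeded, sized, and reproducible", {
  a <- simulate_experiment(seed = 11)
  b <- simulate_experiment(seed = 11)
  c <- simulate_experiment(seed = 12)
  expect_equal(nrow(a), 26 * 4 * 4)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_true(all(a$replicate %in% 1:4) && all(a$explant %in% 1:4))
  expect_error(simulate_experiment(seed = "x"), "seed")
})

test_that("per-treatment tetraploid fractions are multiples of 1/16 in the 4x4 design", {
  rec <- simulate_experiment(seed = 3)
  frac <- tapply(rec$ploidy == "tetraploid",
                 paste(rec$concentration_uM, rec$exposure_h), mean)
  expect_true(all(abs(frac * 16 - round(frac * 16)) < 1e-12))
})

test_that("low-dose simulation yields almost no tetraploids", {
  grid1 <- data.frame(concentration_uM = 5, exposure_h = 24)
  rec <- simulate_experiment(grid1, replicates = 1, explants = 10000, seed = 5)
  expect_lt(mean(rec$ploidy == "tetraploid"), 0.05)
})

test_that("empirical class frequencies recover the analytic probabilities", {
  for (trt in list(c(60, 24), c(100, 10), c(20, 18))) {
    p <- drop(class_probabilities(trt[1], trt[2]))
    grid1 <- data.frame(concentration_uM = trt[1], exposure_h = trt[2])
    rec <- simulate_experiment(grid1, replicates = 1, explants = 10000,
                               seed = 17)
    phat <- c(mean(rec$ploidy == "diploid"), mean(rec$ploidy == "mixoploid"),
              mean(rec$ploidy == "tetraploid"))
    se <- sqrt(p * (1 - p) / 10000)
    expect_true(all(abs(phat - p) <= 3 * se + 1e-12),
                info = paste("treatment", trt[1], trt[2]))
  }
})

test_that("balanced assembly subsamples to equal class sizes", {
  rec <- simulate_experiment(seed = 1)
  d <- assemble_balanced_dataset(rec, per_class = 24, seed = 2)
  expect_s3_class(d, "ploidy_dataset")
  expect_equal(n_instances(d), 72)
  expect_true(all(class_counts(d) == 24))
  expect_identical(assemble_balanced_dataset(rec, 24, seed = 2)$features,
                   d$features)
  expect_equal(n_instances(assemble_balanced_dataset(rec, 0, seed = 1)), 0)
  # deficient class is named in the error
  few <- rec[rec$ploidy != "mixoploid", ]
  few <- rbind(few, rec[rec$ploidy == "mixoploid", ][1:3, ])
  expect_error(assemble_balanced_dataset(few, 24, seed = 1), "mixoploid")
})
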