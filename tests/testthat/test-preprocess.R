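test_that("PCA outlier screen removes a gross outlier and only that point", {
  withr_seed(8)
  x <- cbind(runif(71, 0, 100), runif(71, 0, 36))
  x <- rbind(x, c(1e6, 1e6))
  colnames(x) <- c("concentration_uM", "exposure_h")
  d <- ploidy_dataset(x, rep(ploidy_classes(), length.out = 72))
  res <- pca_outlier_filter(d, alpha = 0.025)
  # independent oracle: classical squared Mahalanobis distance against the
  # chi-square cutoff (identical to summed standardized PC scores)
  md <- stats::mahalanobis(x, colMeans(x), stats::cov(x))
  expect_identical(res$removed, which(md > stats::qchisq(0.975, df = 2)))
  expect_identical(res$removed, 72L)
  expect_equal(n_instances(res$dataset) + length(res$removed), 72)
})

test_that("outlier screen is idempotent and honours alpha -> 0", {
  d <- default_balanced_dataset(seed = 4)
  once <- pca_outlier_filter(d, 0.025)
  twice <- pca_outlier_filter(once$dataset, 0.025)
  expect_length(twice$removed, 0)
  tiny <- pca_outlier_filter(d, 1e-12)
  expect_length(tiny$removed, 0)
  # degenerate covariance is an error
  dd <- ploidy_dataset(cbind(concentration_uM = rep(5, 10),
                             exposure_h = 1:10),
                       rep("diploid", 10))
  expect_error(pca_outlier_filter(dd), "zero variance")
})

test_that("standardizer centers, scales, and inverts losslessly", {
  withr_seed(9)
  x <- cbind(concentration_uM = runif(40, 0, 100),
             exposure_h = runif(40, 0, 36))
  s <- fit_standardizer(x)
  z <- apply_standardizer(s, x)
  expect_true(all(abs(colMeans(z)) < 1e-10))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-10))
  expect_true(all(abs(invert_standardizer(s, z) - x) < 1e-10))
  # identity parameters give the identity transform
  id <- structure(list(mean = c(0, 0), sd = c(1, 1)), class = "standardizer")
  expect_equal(apply_standardizer(id, x), x, ignore_attr = TRUE)
  expect_error(fit_standardizer(cbind(rep(1, 5), 1:5)), "variance")
})

test_that("test-set transformation uses training statistics only", {
  d <- default_balanced_dataset(seed = 5)
  sp <- stratified_split(d, 19, seed = 1)
  s <- fit_standardizer(sp$train)
  z1 <- apply_standardizer(s, sp$test)
  # refit on train only: identical regardless of what the test set holds
  s2 <- fit_standardizer(sp$train$features)
  expect_identical(apply_standardizer(s2, sp$test), z1)
  expect_false(isTRUE(all.equal(colMeans(z1), c(0, 0), tolerance = 1e-8)))
})

test_that("stratified split partitions the dataset with per-class counts", {
  d <- default_balanced_dataset(seed = 6)
  sp <- stratified_split(d, train_per_class = 19, seed = 31)
  expect_equal(n_instances(sp$train), 57)
  expect_equal(n_instances(sp$test), 15)
  expect_true(all(class_counts(sp$train) == 19))
  expect_true(all(class_counts(sp$test) == 5))
  expect_setequal(c(sp$train_idx, sp$test_idx), seq_len(72))
  # determinism and seed sensitivity
  expect_identical(stratified_split(d, 19, seed = 31)$train_idx, sp$train_idx)
  expect_false(identical(stratified_split(d, 19, seed = 32)$train_idx,
                         sp$train_idx))
  # full train -> empty test
  all_in <- stratified_split(d, 24, seed = 1)
  expect_equal(n_instances(all_in$test), 0)
  expect_error(stratified_split(d, 25, seed = 1), "fewer")
})

test_that("CSV round-trip is lossless and parse errors are located", {
  d <- default_balanced_dataset(seed = 7)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ploidy_csv(d, f)
  expect_identical(readLines(f, n = 1), "concentration_uM,exposure_h,ploidy")
  back <- read_ploidy_csv(f)
  expect_equal(back$features, d$features, ignore_attr = TRUE)
  expect_identical(as.character(back$labels), as.character(d$labels))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("concentration_uM,exposure_h,ploidy", "5,12,triploid"), bad)
  expect_error(read_ploidy_csv(bad), "triploid")
  writeLines(c("concentration_uM,exposure_h,ploidy", "x,12,diploid"), bad)
  expect_error(read_ploidy_csv(bad), "row 1")
  writeLines(c("concentration_uM,ploidy", "5,diploid"), bad)
  expect_error(read_ploidy_csv(bad), "missing column")
  writeLines(character(0), bad)
  expect_error(read_ploidy_csv(bad))
})

test_that("split manifest records indices and standardization", {
  d <- default_balanced_dataset(seed = 8)
  sp <- stratified_split(d, 19, seed = 2)
  s <- fit_standardizer(sp$train)
  f <- withr::local_tempfile(fileext = ".json")
  write_split_manifest(sp, s, f)
  m <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(m$seed, 2)
  expect_equal(sort(unname(unlist(m$train_indices))), sort(sp$train_idx))
  expect_equal(unlist(m$standardization$mean), s$mean,
               ignore_attr = TRUE)
})
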