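# Fixtures built in code: no data files.

# Three widely separated 2-D clusters, one per ploidy class, with tiny
# within-cluster jitter. Deterministic given the seed.
cluster_fixture <- function(n_per = 8, spread = 0.05, seed = 42) {
  centers <- rbind(diploid = c(-10, 0), mixoploid = c(10, 0),
                   tetraploid = c(0, 12))
  withr_seed(seed)
  x <- do.call(rbind, lapply(rownames(centers), function(cl) {
    sweep(matrix(rnorm(2 * n_per, sd = spread), ncol = 2), 2,
          centers[cl, ], "+")
  }))
  colnames(x) <- c("concentration_uM", "exposure_h")
  list(x = x, y = factor(rep(rownames(centers), each = n_per),
                         levels = ploidy_classes()))
}

# set.seed without leaking into other tests is unnecessary here (testthat
# runs each file in one session), but keep it explicit and local-feeling
withr_seed <- function(seed) set.seed(seed)

default_balanced_dataset <- function(seed = 1) {
  rec <- simulate_experiment(seed = seed * 101 + 1)
  assemble_balanced_dataset(rec, per_class = 24, seed = seed * 101 + 2)
}

expect_within <- function(x, lo, hi) {
  expect_true(all(x >= lo & x <= hi),
              info = sprintf("values outside [%g, %g]: %s", lo, hi,
                             paste(format(x[x < lo | x > hi]),
                                   collapse = ", ")))
}
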