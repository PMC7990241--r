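test_that("sum normalization rescales every sample to the target total", {
  data <- tibble::tibble(a = c(1, 10), b = c(3, 30), c = c(6, 60))
  out <- normalize_measurements(data, "sum")
  expect_equal(rowSums(as.matrix(out)), c(100, 100))
  expect_equal(unname(unlist(out[1, ])), c(10, 30, 60))
  out2 <- normalize_measurements(data, "sum", sum_target = 1)
  expect_equal(rowSums(as.matrix(out2)), c(1, 1))
})

test_that("reference-sample normalization matches every row sum to the reference", {
  data <- tibble::tibble(a = c(4, 2, 20), b = c(6, 3, 30))
  meta <- tibble::tibble(sample_id = c("R", "S", "T"))
  out <- normalize_measurements(data, "reference_sample",
                                reference_sample = "R", sample_meta = meta)
  # reference row sum 10; S's sum 5 -> doubled, T's sum 50 -> divided by 5
  expect_equal(unname(unlist(out[2, ])), c(4, 6))
  expect_equal(unname(rowSums(as.matrix(out))), rep(10, 3))
  expect_error(
    normalize_measurements(data, "reference_sample",
                           reference_sample = "missing", sample_meta = meta),
    "not found")
})

test_that("weight/volume normalization divides each sample by its mass", {
  data <- tibble::tibble(a = c(2, 9), b = c(4, 3))
  meta <- tibble::tibble(sample_id = c("A", "B"), wt = c(2, 3))
  out <- normalize_measurements(data, "weight_volume", sample_meta = meta,
                                mass_column = "wt")
  expect_equal(out$a, c(1, 3))
  meta_bad <- tibble::tibble(sample_id = c("A", "B"), wt = c(2, 0))
  expect_error(
    normalize_measurements(data, "weight_volume", sample_meta = meta_bad,
                           mass_column = "wt"),
    "positive")
})

test_that("minmax maps each metabolite column onto [0, 1]", {
  data <- tibble::tibble(a = c(2, 4, 6), b = c(10, 30, 20))
  out <- normalize_measurements(data, "minmax")
  expect_equal(out$a, c(0, 0.5, 1))
  expect_equal(out$b, c(0, 1, 0.5))
  const <- tibble::tibble(a = c(1, 1))
  expect_error(normalize_measurements(const, "minmax"), "constant")
})

test_that("log and root transforms apply elementwise", {
  data <- tibble::tibble(x = c(1, 10, 100))
  expect_equal(transform_measurements(data, "log10")$x, c(0, 1, 2))
  expect_equal(transform_measurements(tibble::tibble(x = c(1, 2, 8)),
                                      "log2")$x, c(0, 1, 3))
  expect_equal(transform_measurements(tibble::tibble(x = c(0, 4, 9)),
                                      "sqrt")$x, c(0, 2, 3))
  expect_equal(transform_measurements(tibble::tibble(x = c(-8, 27)),
                                      "cbrt")$x, c(-2, 3))
})

test_that("zeros under log follow the pseudo-count policy; negatives always raise", {
  zero <- tibble::tibble(x = c(0, 10))
  expect_error(transform_measurements(zero, "log10"), "pseudo-count")
  off <- transform_measurements(zero, "log10",
                                pseudo_count_policy = "half_min_positive")
  expect_equal(off$x, log10(c(5, 15)))  # offset = smallest positive / 2
  fx <- transform_measurements(zero, "log2", pseudo_count_policy = "fixed",
                               pseudo_count_value = 1)
  expect_equal(fx$x, log2(c(1, 11)))
  neg <- tibble::tibble(x = c(-1, 2))
  expect_error(transform_measurements(neg, "log10"), "negative")
  expect_error(transform_measurements(neg, "sqrt"), "negative")
})

test_that("scaling formulas match hand computation", {
  expect_equal(scale_measurements(tibble::tibble(x = c(1, 2, 3)),
                                  "autoscale")$x, c(-1, 0, 1))
  # column with sd 4: centered values divided by sqrt(4) = 2 under Pareto
  x <- c(1, 5, 9)  # sd = 4
  expect_equal(scale_measurements(tibble::tibble(x = x), "pareto")$x,
               (x - 5) / 2)
  expect_equal(scale_measurements(tibble::tibble(x = c(2, 4, 6)),
                                  "level")$x, c(-0.5, 0, 0.5))
})

test_that("scaling invariants hold on random matrices", {
  data <- random_positive_matrix(15, 6, seed = 21)
  m <- as.matrix(data)
  tol <- 1e-9

  auto <- as.matrix(scale_measurements(data, "autoscale"))
  expect_lt(max(abs(colMeans(auto))), tol)
  expect_lt(max(abs(apply(auto, 2, sd) - 1)), tol)

  pareto <- as.matrix(scale_measurements(data, "pareto"))
  expect_lt(max(abs(apply(pareto, 2, var) - apply(m, 2, sd)) /
                  apply(m, 2, sd)), tol)

  rng <- as.matrix(scale_measurements(data, "range"))
  expect_lt(max(abs(apply(rng, 2, function(x) diff(range(x))) - 1)), tol)

  lvl <- as.matrix(scale_measurements(data, "level"))
  expect_lt(max(abs(colMeans(lvl))), tol)

  vast <- as.matrix(scale_measurements(data, "vast"))
  target <- abs(colMeans(m) / apply(m, 2, sd))
  expect_lt(max(abs(apply(vast, 2, sd) - target) / target), tol)
})

test_that("scalings commute with sample permutations", {
  data <- random_positive_matrix(12, 4, seed = 31)
  perm <- withr::with_seed(1, sample.int(12))
  for (method in c("autoscale", "pareto", "range", "vast", "level")) {
    direct <- as.matrix(scale_measurements(data, method))[perm, ]
    permed <- as.matrix(scale_measurements(data[perm, ], method))
    expect_equal(direct, permed, ignore_attr = TRUE)
  }
})

test_that("scaling errors name the offending column", {
  data <- tibble::tibble(fine = c(1, 2, 3), flat = c(4, 4, 4))
  expect_error(scale_measurements(data, "autoscale"), "flat")
  expect_error(scale_measurements(data, "range"), "flat")
  centered <- tibble::tibble(ok = c(1, 2, 3), zm = c(-1, 0, 1))
  expect_error(scale_measurements(centered, "level"), "zm")
})

test_that("apply_treatment composes the stages in normalize-transform-scale order", {
  data <- random_positive_matrix(8, 3, seed = 41)
  cfg <- treatment_config(normalization = "sum", transformation = "log10",
                          scaling = "autoscale")
  manual <- data |>
    normalize_measurements("sum") |>
    transform_measurements("log10") |>
    scale_measurements("autoscale")
  expect_equal(apply_treatment(data, cfg), manual)
  # all-none is the identity
  expect_equal(apply_treatment(data, treatment_config()), data,
               ignore_attr = TRUE)
})

test_that("treatment_config enforces its conditional fields", {
  expect_error(treatment_config(normalization = "reference_sample"),
               class = "metabopipe_config_error")
  expect_error(treatment_config(normalization = "weight_volume"),
               class = "metabopipe_config_error")
  expect_error(treatment_config(pseudo_count_policy = "fixed"),
               class = "metabopipe_config_error")
})
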