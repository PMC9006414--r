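test_that("latent vector has unit norm and is seed-deterministic", {
  mu <- make_latent(120, seed = 42)
  expect_equal(sqrt(sum(mu^2)), 1.0, tolerance = 1e-12)
  expect_identical(mu, make_latent(120, seed = 42))
  expect_true(any(mu != make_latent(120, seed = 43)))
  expect_error(make_latent(1, seed = 1), "integer >= 2")
})

test_that("zero-noise generation is exactly rank one per view", {
  spec <- synthetic_spec(n = 15, true_weights = list(c(1, 0, 2), c(0, -1, 1)),
                         noise_level = 0, seed = 5)
  ds <- generate_multiview(spec)
  mu <- make_latent(15, seed = 5)
  for (k in 1:2) {
    expect_equal(ds$views[[k]]$data,
                 tcrossprod(mu, spec$true_weights[[k]]),
                 ignore_attr = TRUE, tolerance = 1e-15)
  }
})

test_that("noise-free Data1 views are exact multiples on the shared block", {
  ds <- generate_multiview(data1_spec(noise_level = 0, seed = 2))
  X1 <- ds$views[[1]]$data; X2 <- ds$views[[2]]$data; X3 <- ds$views[[3]]$data
  expect_equal(X2[, 81:120], 2 * X1[, 81:120], tolerance = 1e-15,
               ignore_attr = TRUE)
  expect_equal(X3[, 81:120], -X1[, 81:120], tolerance = 1e-15,
               ignore_attr = TRUE)
  expect_true(all(X1[, c(1:80, 121:200)] == 0))
})

test_that("generation is bit-reproducible and respects the noise variance", {
  spec <- data1_spec(noise_level = 0.1, seed = 11)
  ds <- generate_multiview(spec)
  expect_identical(ds$views[[2]]$data, generate_multiview(spec)$views[[2]]$data)
  mu <- make_latent(120, seed = 11)
  res <- ds$views[[1]]$data - tcrossprod(mu, spec$true_weights[[1]])
  # 24000 residuals: sample variance within Monte-Carlo error of e
  expect_equal(mean(res^2), 0.1, tolerance = 0.01)
})

test_that("replicate-averaged views converge on the rank-one signal", {
  base <- synthetic_spec(n = 10, true_weights = list(c(2, 0, -1), c(0, 1, 1)),
                         noise_level = 0.5, seed = 1)
  R <- 200
  acc <- matrix(0, 10, 3)
  for (r in seq_len(R)) {
    sp <- synthetic_spec(10, base$true_weights, 0.5, seed = 1000 + r)
    acc <- acc + generate_multiview(sp)$views[[1]]$data
  }
  avg <- acc / R
  # each replicate has its own latent; compare against per-replicate signals
  sig <- matrix(0, 10, 3)
  for (r in seq_len(R)) {
    sig <- sig + tcrossprod(make_latent(10, seed = 1000 + r),
                            base$true_weights[[1]])
  }
  sig <- sig / R
  mc_se <- sqrt(0.5 / R)
  expect_true(max(abs(avg - sig)) < 3 * mc_se)
})

test_that("the first benchmark design has the stated blocks", {
  spec <- data1_spec(0.01, seed = 1)
  expect_equal(spec$n, 120L); expect_equal(spec$K, 3L); expect_equal(spec$p, 200L)
  v1 <- spec$true_weights[[1]]; v2 <- spec$true_weights[[2]]
  v3 <- spec$true_weights[[3]]
  expect_equal(which(v1 != 0), 81:120)
  expect_true(all(v1[81:120] == 1))
  expect_true(all(v2[81:120] == 2))
  expect_true(all(v3[81:120] == -1))
  expect_identical(which(v1 != 0), which(v2 != 0))
  expect_identical(which(v1 != 0), which(v3 != 0))
})

test_that("the second benchmark design has the stated blocks and overlaps", {
  spec <- data2_spec(0.01, seed = 1)
  v1 <- spec$true_weights[[1]]; v2 <- spec$true_weights[[2]]
  v3 <- spec$true_weights[[3]]
  expect_equal(sum(v1 != 0), 60L)
  expect_equal(sum(v2 != 0), 90L)
  expect_equal(sum(v3 != 0), 50L)
  expect_equal(which(v1 != 0), 76:135)
  expect_equal(which(v2 != 0), c(41:100, 141:170))
  expect_equal(which(v3 != 0), 71:120)
  expect_true(all(v2[v2 != 0] == 2))
  expect_true(all(v3[v3 != 0] == -2))
  sup <- true_supports(spec)
  expect_equal(sup$shared, 76:100)
  expect_length(sup$shared, 25L)
  # v2's second block is private to view 2
  expect_length(intersect(141:170, which(v1 != 0)), 0L)
  expect_length(intersect(141:170, which(v3 != 0)), 0L)
  expect_true(all(141:170 %in% sup$private[[2]]))
})

test_that("invalid specifications are rejected", {
  expect_error(synthetic_spec(1, list(c(1, 0), c(0, 1)), 0.1, 1))
  expect_error(synthetic_spec(10, list(c(1, 0), c(0, 1, 1)), 0.1, 1),
               "same length")
  expect_error(synthetic_spec(10, list(c(1, 0), c(0, 1)), -0.1, 1))
  expect_error(data1_spec(noise_level = -1))
})

test_that("a written synthetic dataset round-trips through its files", {
  spec <- synthetic_spec(n = 8, true_weights = list(c(1, 0, 0, 2), rep(1, 4)),
                         noise_level = 0.2, seed = 3)
  ds <- generate_multiview(spec)
  dir <- withr::local_tempdir()
  paths <- write_synthetic(ds, dir)
  expect_length(paths, 3L)  # two view CSVs + spec.json
  back <- read_view(file.path(dir, "view1.csv"))
  expect_equal(back$data, ds$views[[1]]$data, ignore_attr = TRUE)
  side <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  expect_equal(side$n, 8)
  expect_equal(side$noise_level, 0.2)
  expect_equal(side$true_weights$support[[1]], c(1, 4))
  expect_equal(side$true_weights$values[[2]], rep(1, 4))
})
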