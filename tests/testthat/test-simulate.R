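test_that("similarity generator reproduces its linear mixture exactly at zero noise", {
  ds <- gen_similarity(n_participants = 5, weights = c(nST = 0.12, ET = 0.06),
                       intercept = 0.05, noise_sd = 0, seed = 1)
  expect_equal(dim(ds$vectors), c(5L, 21L))
  target <- reconstruct(list(betas = c(nST = 0.12, ET = 0.06), intercept = 0.05),
                        default_library)
  for (i in 1:5) expect_equal(unname(ds$vectors[i, ]), unname(target))
  # determinism
  ds2 <- gen_similarity(n_participants = 5, weights = c(nST = 0.12, ET = 0.06),
                        intercept = 0.05, noise_sd = 0, seed = 1)
  expect_identical(ds$vectors, ds2$vectors)
  expect_error(gen_similarity(weights = c(bogus = 1)), "unknown")
  expect_error(gen_similarity(noise_sd = -1), "noise_sd")
})

test_that("stacked OLS recovers generator weights within analytic error", {
  ds <- gen_similarity(n_participants = 60, weights = c(nST = 0.12, ET = 0.06),
                       intercept = 0.05, noise_sd = 0.02, seed = 20)
  f <- fit_model(ds$vectors, default_library, c("nST", "ET"))
  # closed-form OLS sampling distribution: se = sigma * sqrt((X'X)^-1_kk)
  P <- sapply(default_library[c("nST", "ET")], function(p) p$vector)
  X <- cbind(1, P[rep(1:21, 60), ])
  se <- 0.02 * sqrt(diag(solve(crossprod(X))))
  expect_lt(abs(f$betas["nST"] - 0.12), 3 * se[2])
  expect_lt(abs(f$betas["ET"] - 0.06), 3 * se[3])
  expect_lt(abs(f$intercept - 0.05), 3 * se[1])
})

test_that("generator cell means obey the law of large numbers", {
  ds <- gen_similarity(n_participants = 5000, noise_sd = 0.05, seed = 31)
  target <- reconstruct(list(betas = c(nST = 0.12, ET = 0.06), intercept = 0.05),
                        default_library)
  err <- abs(colMeans(ds$vectors) - target)
  expect_true(all(err < 3 * 0.05 / sqrt(5000)))
})

test_that("voxel generator emits design-sized patterns with matching similarity structure", {
  # zero unstructured noise, one planted component spanning all trials:
  # +1-support cells of the condensed similarity must dominate 0-support cells
  ds <- gen_voxel_patterns(n_participants = 2, weights = c(ET = 0.3),
                           intercept = 0, n_voxels = 500,
                           shared_var = 1, noise_var = 0, seed = 2)
  expect_length(ds$patterns, 2L)
  expect_equal(dim(ds$patterns[[1]]$values), c(36L, 500L))
  for (p in ds$patterns) {
    v <- vectorize(condense(trial_similarity(p), default_design))
    on <- default_library$ET$vector == 1
    expect_gt(min(v[on]), max(v[!on]))
  }
  # deterministic in (config, seed)
  ds2 <- gen_voxel_patterns(n_participants = 2, weights = c(ET = 0.3),
                            intercept = 0, n_voxels = 500,
                            shared_var = 1, noise_var = 0, seed = 2)
  expect_identical(ds$patterns[[1]]$values, ds2$patterns[[1]]$values)
})

test_that("condensed similarity converges to the target mixture at many voxels", {
  ds <- gen_voxel_patterns(n_participants = 1, n_voxels = 5000, seed = 3)
  v <- vectorize(condense(trial_similarity(ds$patterns[[1]]), default_design))
  target <- reconstruct(list(betas = c(nST = 0.12, ET = 0.06), intercept = 0.05),
                        default_library)
  expect_gt(cor(v, target), 0.9)
})

test_that("empirical trial covariance converges to the PSD-projected target", {
  ds <- gen_voxel_patterns(n_participants = 1, n_voxels = 20000, seed = 4)
  target6 <- devectorize(reconstruct(list(betas = c(nST = 0.12, ET = 0.06),
                                          intercept = 0.05), default_library))
  ci <- match(default_design$trials$condition_id,
              default_design$conditions$condition_id)
  sigma <- target6[ci, ci] + diag(36)  # PSD already; noise_var = 1
  emp <- tcrossprod(ds$patterns[[1]]$values) / 20000
  expect_lt(max(abs(emp - sigma)), 0.05)
  expect_lt(ds$truth$psd_error, 1e-8)
})

test_that("fixture export round-trips through the package readers", {
  dir <- withr::local_tempdir()
  vds <- gen_voxel_patterns(n_participants = 2, n_voxels = 10, seed = 5)
  export_fixtures(vds, dir)
  pats <- load_patterns(file.path(dir, c("sub1_patterns.csv", "sub2_patterns.csv")),
                        file.path(dir, "trial_metadata.csv"))
  expect_equal(unname(pats[[1]]$values), unname(vds$patterns[[1]]$values),
               tolerance = 1e-12)
  meta <- utils::read.csv(file.path(dir, "trial_metadata.csv"))
  expect_equal(nrow(meta), 36L)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(truth$seed, 5L)
  expect_equal(truth$weights$nST, 0.12)

  sds <- gen_similarity(n_participants = 3, seed = 6)
  export_fixtures(sds, dir)
  back <- read_similarity(file.path(dir, "similarity.csv"))
  expect_equal(unname(back), unname(sds$vectors), tolerance = 1e-12)
})
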