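test_that("a unique noise-free predictor is recovered on a single path", {
  y <- gen_similarity(n_participants = 10, weights = c(ET = 0.5),
                      intercept = 0.2, noise_sd = 0, seed = 1)$vectors
  res <- gbfs_search(y, default_library)
  expect_equal(res$final_set, "ET")
  expect_equal(res$n_path, 1L)
  # second level additions were all rejected
  expect_equal(nrow(res$paths[[1]]$accepted), 1L)
  expect_length(res$paths[[1]]$levels, 2L)
  tr <- search_trace(res)
  expect_equal(which.min(unlist(tr[1, names(default_library)])),
               c(ET = 1L))
})

test_that("the two-component simulation is recovered in acceptance order", {
  y <- gen_similarity(n_participants = 60, weights = c(nST = 0.12, ET = 0.06),
                      intercept = 0.05, noise_sd = 0.02, seed = 42)$vectors
  res <- gbfs_search(y, default_library)
  expect_equal(res$final_set, c("nST", "ET"))  # order of acceptance
  # level-2 trace: ET beats every other addition
  lev2 <- res$paths[[1]]$levels[[2]]
  expect_equal(names(which.min(lev2)), "ET")
})

test_that("near-tied level-1 candidates branch into equivalent paths", {
  y <- gen_similarity(n_participants = 20, weights = c(FS = 0.3),
                      intercept = 0.1, noise_sd = 0.01, seed = 7)$vectors
  lib <- default_library
  twin <- lib$FS
  twin$name <- "FS2"
  lib2 <- structure(c(unclass(lib), list(FS2 = twin)), class = "poi_library")
  res <- gbfs_search(y, lib2)
  expect_equal(res$n_path, 2L)
  terminal <- vapply(res$paths, `[[`, 0, "bic")
  expect_equal(terminal[1], terminal[2], tolerance = 1e-9)
})

test_that("every accepted step drops BIC by more than the acceptance margin", {
  set.seed(91)
  for (i in 1:5) {
    w <- runif(2, 0.03, 0.15)
    y <- gen_similarity(n_participants = 30,
                        weights = setNames(w, sample(names(default_library), 2)),
                        intercept = 0.05, noise_sd = 0.03, seed = 100 + i)$vectors
    res <- gbfs_search(y, default_library)
    for (p in res$paths) {
      if (nrow(p$accepted)) expect_true(all(p$accepted$delta > 2))
    }
    if (length(res$final_set)) {
      # telescoping: final BIC beats the intercept-only baseline by > 2
      expect_lt(res$final_fit$bic, res$baseline_none$bic - 2)
    }
    # terminal fit has the minimum BIC across completed paths
    expect_equal(res$final_fit$bic, min(vapply(res$paths, `[[`, 0, "bic")),
                 tolerance = 1e-9)
  }
})

test_that("greedy terminal BIC matches brute-force best-subset on friendly data", {
  small_lib <- default_library[c("ET", "nST", "ST", "AP", "AB", "TV", "FS", "VE")]
  y <- gen_similarity(n_participants = 25, weights = c(nST = 0.12, ET = 0.06),
                      intercept = 0.05, noise_sd = 0.02, seed = 5,
                      library = default_library)$vectors
  res <- gbfs_search(y, small_lib)
  oracle <- best_subset_oracle(y, small_lib)
  expect_setequal(res$final_set, oracle$set)
  expect_equal(res$final_fit$bic, oracle$bic, tolerance = 1e-6)
  # greedy can never beat exhaustive search
  set.seed(17)
  y2 <- matrix(rnorm(10 * 21, 0.05, 0.05), 10, 21)
  res2 <- gbfs_search(y2, small_lib)
  oracle2 <- best_subset_oracle(y2, small_lib)
  expect_gte(res2$final_fit$bic, oracle2$bic - 1e-9)
})

test_that("search output is invariant to library ordering", {
  y <- gen_similarity(n_participants = 40, weights = c(nST = 0.12, ET = 0.06),
                      intercept = 0.05, noise_sd = 0.02, seed = 13)$vectors
  res1 <- gbfs_search(y, default_library)
  shuffled <- default_library[rev(seq_along(default_library))]
  res2 <- gbfs_search(y, shuffled)
  expect_setequal(res1$final_set, res2$final_set)
  expect_equal(res1$final_fit$bic, res2$final_fit$bic, tolerance = 1e-12)
  expect_equal(res1$n_path, res2$n_path)
})

test_that("degenerate search inputs are rejected", {
  y <- matrix(rnorm(2 * 21), 2, 21)
  expect_error(gbfs_search(y, structure(list(), class = "poi_library")), "empty")
})

test_that("null data select no POI", {
  set.seed(3)
  y <- matrix(rnorm(30 * 21, 0.05, 0.05), 30, 21)
  res <- gbfs_search(y, default_library)
  # pure noise: with high probability nothing clears the Delta-BIC bar; if
  # anything does, the telescoping invariant must still hold
  if (length(res$final_set) == 0) {
    expect_equal(res$final_fit$bic, res$baseline_none$bic)
    expect_equal(res$n_path, 1L)
  } else {
    expect_lt(res$final_fit$bic, res$baseline_none$bic - 2)
  }
})

test_that("the search trace carries None/All reference columns", {
  y <- gen_similarity(n_participants = 15, seed = 2)$vectors
  res <- gbfs_search(y, default_library)
  tr <- search_trace(res)
  expect_true(all(c("None", "All", "included", names(default_library)) %in% names(tr)))
  expect_equal(unique(tr$None), res$baseline_none$bic)
  expect_equal(unique(tr$All), res$baseline_all$bic)
  expect_equal(tr$included[tr$level == 1], rep("-", sum(tr$level == 1)))
})
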