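test_that("reconstruction is the weighted POI sum plus intercept", {
  lib <- default_library
  flat <- reconstruct(list(betas = list(), intercept = 0.3), lib)
  expect_equal(unname(flat), rep(0.3, 21))
  fs <- reconstruct(list(betas = c(FS = 1), intercept = 0), lib)
  expect_equal(unname(fs), unname(lib$FS$vector))
  expect_equal(sum(fs == 1), 6)
  # three-component mixture checked cellwise by hand on spot cells
  w <- list(nST = 0.13, ET = 0.055, ST = 0.025)
  rec <- reconstruct(list(betas = w, intercept = 0.05), lib)
  # P+1:P+1 — touch (nST), same task (ET), same touch type (ST)
  expect_equal(unname(rec["P+1:P+1"]), 0.05 + 0.13 + 0.055 + 0.025)
  # P+1:P- — same task only
  expect_equal(unname(rec["P+1:P-"]), 0.05 + 0.055)
  # P+1:B+1 — touch across tasks (nST only)
  expect_equal(unname(rec["P+1:B+1"]), 0.05 + 0.13)
  expect_error(reconstruct(list(betas = c(zz = 1), intercept = 0), lib), "unknown")
})

test_that("hold-out regression has df (1, 21n - 2) and matches the closed form", {
  lib <- default_library
  rec <- reconstruct(list(betas = c(nST = 0.12, ET = 0.06), intercept = 0.05), lib)
  ho7 <- gen_similarity(n_participants = 7, seed = 4)$vectors
  hf <- holdout_fit(rec, ho7)
  expect_equal(hf$df, c(1L, 145L))
  # perfect hold-out: slope 1, r2 1
  exact <- matrix(rec, 3, 21, byrow = TRUE)
  hf2 <- holdout_fit(rec, exact)
  expect_equal(hf2$r2, 1, tolerance = 1e-12)
  expect_equal(hf2$recon_beta, 1, tolerance = 1e-12)
  # scaled + shifted hold-out recovers the slope; df = (1, 61) at 3 participants
  set.seed(6)
  noisy <- matrix(2 * rep(rec, 3) + 0.1 + rnorm(63, 0, 1e-2), 3, 21, byrow = TRUE)
  hf3 <- holdout_fit(rec, noisy)
  expect_equal(hf3$df, c(1L, 61L))
  expect_equal(hf3$recon_beta, 2, tolerance = 0.05)
  # closed-form simple-regression oracle
  x <- rep(rec, 3); y <- as.vector(t(noisy))
  b <- cov(x, y) / var(x)
  expect_equal(hf3$recon_beta, b, tolerance = 1e-12)
  expect_equal(hf3$r2, cor(x, y)^2, tolerance = 1e-12)
  f_oracle <- hf3$r2 / (1 - hf3$r2) * 61
  expect_equal(hf3$f_stat, f_oracle, tolerance = 1e-8)
  expect_error(holdout_fit(rep(0.3, 21), ho7), "degenerate predictor")
})

test_that("mccv is reproducible and validates its configuration", {
  y <- gen_similarity(n_participants = 20, seed = 10)$vectors
  cv1 <- mccv(y, default_library, n_iter = 4, n_rs = 12, n_ho = 5, seed = 99)
  cv2 <- mccv(y, default_library, n_iter = 4, n_rs = 12, n_ho = 5, seed = 99)
  expect_identical(cv1$iterations, cv2$iterations)
  cv3 <- mccv(y, default_library, n_iter = 4, n_rs = 12, n_ho = 5, seed = 98)
  expect_false(identical(cv1$iterations[[1]]$rs_ids, cv3$iterations[[1]]$rs_ids))
  expect_error(mccv(y, default_library, n_rs = 18, n_ho = 5), "exceeds")
  expect_error(mccv(y, default_library, n_iter = 0, n_rs = 10, n_ho = 5), "n_iter")
})

test_that("mccv summaries implement the chance-threshold bookkeeping", {
  y <- gen_similarity(n_participants = 20, noise_sd = 0.01, seed = 12)$vectors
  cv <- mccv(y, default_library, n_iter = 6, n_rs = 14, n_ho = 5, seed = 3)
  s <- summarize_mccv(cv)
  # chance threshold = mean selected-set size / library size
  expect_equal(s$chance_threshold, s$mean_n_poi / 13)
  expect_true(all(s$poi$prop_identified >= 0 & s$poi$prop_identified <= 1))
  # POIs never selected report no beta
  never <- s$poi$prop_identified == 0
  expect_true(all(is.na(s$poi$mean_beta[never])))
  # identical selections across iterations average to their common betas
  sets <- vapply(cv$iterations, function(it) paste(sort(it$poi_set), collapse = "+"), "")
  if (length(unique(sets)) == 1) {
    b <- rowMeans(vapply(cv$iterations, function(it) it$betas[c("nST", "ET")], numeric(2)))
    expect_equal(s$poi$mean_beta[match(c("nST", "ET"), s$poi$poi)], unname(b))
  }
})

test_that("reconstruction closes the loop with the originating fit", {
  y <- gen_similarity(n_participants = 25, seed = 15)$vectors
  f <- fit_model(y, default_library, c("nST", "ET"))
  rec <- reconstruct(f, default_library)
  pred_rss <- sum((as.vector(t(y)) - rep(rec, 25))^2)
  tss <- sum((as.vector(t(y)) - mean(y))^2)
  expect_equal(1 - pred_rss / tss, f$r2, tolerance = 1e-10)
})

test_that("n-path comparison matches textbook ANOVA and t values", {
  res <- npath_compare(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  # hand-computed: SSB = 13.5, SSW = 4, df (1,4) -> F = 13.5
  expect_equal(res$f_stat, 13.5, tolerance = 1e-12)
  expect_equal(res$df, c(1L, 4L))
  t_hand <- (2 - 5) / sqrt(1 * (1 / 3 + 1 / 3))  # pooled var = 1
  expect_equal(res$pairwise$t_stat, t_hand, tolerance = 1e-12)
  expect_equal(res$f_stat, t_hand^2, tolerance = 1e-10)
  expect_equal(res$pairwise$p_bonferroni, min(1, res$pairwise$p_raw * 1))

  # degenerate: identical constant groups
  flat <- npath_compare(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_equal(flat$f_stat, 0)
  expect_equal(flat$p_value, 1)
  expect_true(all(flat$pairwise$p_bonferroni == 1))

  # numerator df is groups - 1; Bonferroni multiplies by the pair count
  set.seed(8)
  nine <- lapply(1:9, function(i) rpois(30, 2) + 1)
  names(nine) <- paste0("roi", 1:9)
  res9 <- npath_compare(nine)
  expect_equal(res9$df[1], 8L)
  expect_equal(nrow(res9$pairwise), choose(9, 2))
  expect_equal(res9$pairwise$p_bonferroni,
               pmin(1, res9$pairwise$p_raw * choose(9, 2)))
  expect_error(npath_compare(list(a = 1:3)), ">= 2 groups")
})
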