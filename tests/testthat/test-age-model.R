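make_linear_table <- function(n = 112, seed = 1, noise = 0.05) {
  set.seed(seed)
  days <- rep(c(0, 2, 5, 7, 10, 14, 21, 28), each = n / 8)
  tab <- as.data.frame(lapply(feature_names(), function(f) {
    days + rnorm(n, sd = noise)
  }))
  names(tab) <- feature_names()
  tab$dpn <- days
  tab
}

test_that("standardization matches Eq-style sample-SD z-scores", {
  tab <- data.frame(x = c(1, 2, 3), dpn = c(0, 2, 5))
  out <- standardize(tab)
  expect_equal(out$table$x, c(-1, 0, 1))
  # round trip to 1e-12
  back <- unstandardize(out$table$x, out$params, column = "x")
  expect_equal(back, c(1, 2, 3), tolerance = 1e-12)
  # applying stored params to new data uses those params, not the new moments
  out2 <- standardize(data.frame(x = c(10, 20)), params = out$params,
                      include_dpn = FALSE)
  expect_equal(out2$table$x, (c(10, 20) - 2) / 1)
  expect_error(standardize(data.frame(x = c(5, 5, 5), dpn = c(0, 2, 5))),
               "constant")
})

test_that("splits are deterministic, disjoint, exhaustive and sized 78/17/17", {
  tab <- make_linear_table()
  a <- split_table(tab, seed = 7)
  b <- split_table(tab, seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a$train), 78)
  expect_equal(nrow(a$valid), 17)
  expect_equal(nrow(a$test), 17)
  key <- function(d) sort(do.call(paste, d))
  expect_identical(key(rbind(a$train, a$valid, a$test)), key(tab))
  # every split sees both young and old animals (day stratification)
  for (s in a) {
    expect_true(min(s$dpn) <= 5)
    expect_true(max(s$dpn) >= 21)
  }
  # degenerate fractions put everything in train
  all_train <- split_table(tab, fractions = c(1, 0, 0), seed = 1)
  expect_equal(nrow(all_train$train), nrow(tab))
  expect_equal(nrow(all_train$valid), 0)
})

test_that("the network class recovers a noise-free linear mapping", {
  tab <- make_linear_table(noise = 0)
  sp <- split_table(tab, seed = 1)
  # noiseless task: drop the default regularization so capacity is what is
  # measured, not the weight penalty
  m <- train_mlp(sp$train, sp$valid, sp$test, seed = 1, decay = 1e-5)
  expect_gte(m$report$test$R2, 0.999)
  # definitional identity on every split
  for (s in m$report) {
    if (s$n > 0) expect_equal(s$RMSE^2 * s$n, s$SSE, tolerance = 1e-9)
  }
  expect_error(train_mlp(transform(sp$train, dpn = 5)), "zero-variance")
})

test_that("training is reproducible and predict validates its inputs", {
  tab <- make_linear_table(noise = 0.3)
  sp <- split_table(tab, seed = 2)
  m1 <- train_mlp(sp$train, sp$valid, seed = 9, n_starts = 3)
  m2 <- train_mlp(sp$train, sp$valid, seed = 9, n_starts = 3)
  expect_identical(m1$net$wts, m2$net$wts)
  expect_error(predict(m1, sp$test[, 1:5]), "missing feature")
  # snap mode lands on sampled days only
  snapped <- predict(m1, sp$test, snap = TRUE)
  expect_true(all(snapped %in% c(0, 2, 5, 7, 10, 14, 21, 28)))
})

test_that("sensitivity ratios separate signal, noise and duplicates", {
  set.seed(4)
  n <- 112
  days <- rep(c(0, 2, 5, 7, 10, 14, 21, 28), each = 14)
  tab <- data.frame(signal = days + rnorm(n, sd = 0.3),
                    noise1 = rnorm(n), noise2 = rnorm(n))
  tab$dup <- tab$signal + rnorm(n, sd = 1e-3)
  tab$dpn <- days
  feats <- c("signal", "noise1", "noise2", "dup")
  sp <- split_table(tab, seed = 4)
  m <- train_mlp(sp$train, sp$valid, features = feats, seed = 4, n_starts = 5)
  sens <- sensitivity_analysis(m, sp$train, sp$valid, mode = "retrain",
                               seed = 4)
  r <- setNames(sens$ratio, sens$feature)
  # removing one of an (almost) duplicated pair costs nothing
  expect_lte(r[["signal"]], 1.05)
  expect_lte(r[["dup"]], 1.05)
  # a noise-only feature sits near 1 in permutation mode across seeds
  noise_ratios <- unlist(lapply(1:10, function(s) {
    ps <- sensitivity_analysis(m, sp$train, sp$valid, mode = "permute",
                               seed = s)
    ps$ratio[ps$feature %in% c("noise1", "noise2")]
  }))
  expect_true(all(noise_ratios >= 0.9 & noise_ratios <= 1.1))
  # with no duplicate, the sole signal carrier tops the report
  tab2 <- tab[c("signal", "noise1", "noise2", "dpn")]
  sp2 <- split_table(tab2, seed = 5)
  m2 <- train_mlp(sp2$train, sp2$valid,
                  features = c("signal", "noise1", "noise2"), seed = 5,
                  n_starts = 5)
  s2 <- sensitivity_analysis(m2, sp2$train, sp2$valid, seed = 5)
  expect_identical(s2$feature[which.max(s2$ratio)], "signal")
  expect_gt(max(s2$ratio), 2)
})

test_that("threshold pruning of the published ratios drops exactly four", {
  rep_tab <- published_sensitivity()
  tab <- make_linear_table(noise = 0.3)
  pr <- prune_and_retrain(tab, rep_tab, threshold = 1.1, seed = 1,
                          n_starts = 3)
  expect_setequal(pr$dropped, c("CI_Raman", "Ca", "C", "CI_FTIR"))
  expect_equal(length(pr$kept), 9)
  expect_equal(length(pr$model$features), 9)
  # threshold 0 drops nothing; 1.3 still drops only the same four
  pr0 <- prune_and_retrain(tab, rep_tab, threshold = 0, seed = 1, n_starts = 1)
  expect_identical(pr0$dropped, character(0))
  pr13 <- prune_and_retrain(tab, rep_tab, threshold = 1.3, seed = 1,
                            n_starts = 1)
  expect_setequal(pr13$dropped, c("CI_Raman", "Ca", "C", "CI_FTIR"))
  expect_error(prune_and_retrain(tab, rep_tab, threshold = 10), "refusing")
})

test_that("day-28 trajectory means predict near day 28", {
  cfg <- sim_config(seed = 17, noise_scale = 1)
  tab <- simulate_feature_table(cfg)
  sp <- split_table(tab, seed = 17)
  m <- train_mlp(sp$train, sp$valid, sp$test, seed = 17)
  tr <- default_trajectories()
  row <- as.data.frame(lapply(tr, function(t) traj_at(t, 28)))
  names(row) <- names(tr)
  expect_lt(abs(predict(m, row) - 28), 2)
  # a training row on a well-fit model comes back within a day
  expect_lt(abs(predict(m, sp$train[1, ]) - sp$train$dpn[1]), 1)
})

test_that("growth search prefers moderate capacity and penalizes pure noise", {
  tab <- make_linear_table(noise = 0.3)
  sp <- split_table(tab, seed = 3)
  gs <- growth_search(sp$train, sp$valid, hidden_range = 1:8, seeds = 1L,
                      n_starts = 3)
  expect_true(gs$best_hidden %in% 1:8)
  expect_equal(nrow(gs$curve), 8)
  expect_gte(gs$best_model$report$valid$R2, max(gs$curve$valid_R2) - 1e-9)
  # pure-noise target: validation R2 stays far from 1
  set.seed(8)
  noise_tab <- tab
  noise_tab$dpn <- sample(noise_tab$dpn)
  spn <- split_table(noise_tab, seed = 8)
  gsn <- growth_search(spn$train, spn$valid, hidden_range = c(1, 4, 8),
                       seeds = 1L, n_starts = 2)
  expect_lt(max(gsn$curve$valid_R2), 0.5)
})
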