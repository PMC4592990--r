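test_that("CV plans stratify 80/20 within family, reproducibly", {
  phen <- data.frame(line = paste0("l", 1:50),
                     family = rep(c("A", "B", "C", "D", "E"), each = 10),
                     value = rnorm(50))
  plan <- make_cv_plan(phen, n_repeats = 4, train_fraction = 0.8, seed = 9)
  for (sp in plan$splits) {
    expect_setequal(c(sp$train, sp$test), phen$line)
    expect_length(intersect(sp$train, sp$test), 0)
    cnt <- table(phen$family[match(sp$train, phen$line)])
    expect_true(all(cnt == 8))
  }
  plan2 <- make_cv_plan(phen, 4, 0.8, seed = 9)
  expect_identical(plan$splits, plan2$splits)
  plan3 <- make_cv_plan(phen, 4, 0.8, seed = 10)
  expect_false(identical(plan$splits, plan3$splits))
  expect_true(all(table(phen$family[match(plan3$splits[[1]]$train,
                                          phen$line)]) == 8))
})

test_that("undersized families are refused by name", {
  phen <- data.frame(line = paste0("l", 1:13),
                     family = c(rep("A", 10), rep("tiny", 3)),
                     value = rnorm(13))
  expect_error(make_cv_plan(phen, 2, 0.8, 1), "tiny")
})

test_that("prediction R2 is the signed squared Pearson correlation", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(prediction_r2(x, x), 1.0)
  expect_equal(prediction_r2(x, 2 + 3 * x), 1.0)
  # exact r = -0.5 construction
  a <- c(1, -1, 0)
  b <- c(-1, 0, 1)
  expect_equal(cor(a, b), -0.5)
  expect_equal(prediction_r2(a, b), -0.25)
  expect_error(prediction_r2(x, rep(1, 5)), "zero variance")
  expect_error(prediction_r2(x[1:2], x[1:2]), "3 pairs")
})

test_that("within-family R2 averages over repeats then families", {
  phen <- data.frame(line = paste0("l", 1:12),
                     family = rep(c("A", "B"), each = 6),
                     value = c(1, 2, 3, 4, 5, 6, 2, 4, 6, 8, 10, 12))
  perfect <- prediction_set(phen$line, phen$family, phen$value)
  res <- within_family_r2(list(perfect, perfect), phen)
  expect_equal(res$per_family$r2, c(1, 1))
  expect_equal(res$mean_r2, 1)
  # second repeat with a weaker, family-specific signal
  set.seed(91)
  noisy <- prediction_set(phen$line, phen$family,
                          phen$value + rnorm(12, sd = 2))
  res2 <- within_family_r2(list(perfect, noisy), phen)
  rA <- prediction_r2(phen$value[1:6], noisy$predicted[1:6])
  expect_equal(res2$per_family$r2[1], mean(c(1, rA)))
  # constant predictions surface as a missing cell, not a crash
  const <- prediction_set(phen$line, phen$family, rep(3, 12))
  res3 <- within_family_r2(list(perfect, const), phen)
  expect_equal(res3$per_family$n_repeats, c(1L, 1L))
})

test_that("the error decomposition identity holds exactly per line", {
  set.seed(93)
  phen <- data.frame(line = paste0("l", 1:30), family = "A",
                     value = rnorm(30))
  preds <- lapply(1:6, function(r)
    prediction_set(phen$line, phen$family, phen$value + rnorm(30)))
  dec <- decompose_error(preds, phen, outlier_guard = FALSE)
  with(dec$per_line, expect_equal(bias2_plus_irreducible + variance, mse,
                                  tolerance = 1e-10))
  expect_equal(dec$bias2_plus_irreducible + dec$variance, dec$mse,
               tolerance = 1e-10)
})

test_that("perfect and offset predictions decompose as expected", {
  phen <- data.frame(line = paste0("l", 1:10), family = "A",
                     value = rnorm(10))
  exact <- lapply(1:3, function(r)
    prediction_set(phen$line, phen$family, phen$value))
  d0 <- decompose_error(exact, phen, outlier_guard = FALSE)
  expect_equal(d0$bias2_plus_irreducible, 0)
  expect_equal(d0$variance, 0)
  offset <- lapply(1:3, function(r)
    prediction_set(phen$line, phen$family, phen$value + 1.5))
  d1 <- decompose_error(offset, phen, outlier_guard = FALSE)
  expect_equal(d1$bias2_plus_irreducible, 1.5^2)
  expect_equal(d1$variance, 0)
})

test_that("iid prediction noise lands in the variance term at the 1/R rate", {
  set.seed(95)
  phen <- data.frame(line = paste0("l", 1:200), family = "A",
                     value = rnorm(200))
  R <- 40
  sigma <- 0.8
  preds <- lapply(seq_len(R), function(r)
    prediction_set(phen$line, phen$family, phen$value + rnorm(200, sd = sigma)))
  dec <- decompose_error(preds, phen, outlier_guard = FALSE)
  expect_lt(abs(dec$variance - sigma^2 * (1 - 1 / R)), 0.08)
  expect_lt(dec$bias2_plus_irreducible, 3 * sigma^2 / R)
})

test_that("the outlier guard excludes beyond 100 SEM and reports the count", {
  phen <- data.frame(line = paste0("l", 1:100), family = "A",
                     value = rnorm(100))
  base <- lapply(1:2, function(r)
    prediction_set(phen$line, phen$family, phen$value))
  spiked <- base
  spiked[[2]]$predicted[1] <- 1e6
  d <- decompose_error(spiked, phen, outlier_guard = TRUE)
  expect_equal(d$n_excluded_outliers, 1L)
  d2 <- decompose_error(spiked, phen, outlier_guard = FALSE)
  expect_equal(d2$n_excluded_outliers, 0L)
  expect_gt(d2$mse, d$mse)
})

test_that("RMIP is the selected-and-tested proportion under both denominators", {
  universe <- paste0("m", 1:4)
  recs <- lapply(1:10, function(r) {
    list(tested = if (r <= 5) universe else c("m1", "m2", "m4"),
         selected = c(if (r <= 7) "m1", if (r <= 4 && r <= 5) "m3"))
  })
  tab <- rmip(recs, universe)
  expect_equal(tab$rmip[tab$marker == "m1"], 0.7)
  expect_equal(tab$rmip[tab$marker == "m3"], 0.4)
  expect_equal(tab$rmip[tab$marker == "m2"], 0)
  tab2 <- rmip(recs, universe, "tested_samples")
  expect_equal(tab2$rmip[tab2$marker == "m3"], 4 / 5)
  expect_true(all(tab$rmip >= 0 & tab$rmip <= 1))
  bad <- list(list(tested = "zz", selected = "zz"))
  expect_error(rmip(bad, universe), "outside the universe")
})
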