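make_blocks <- function(X) {
  b <- lapply(seq_len(ncol(X)), function(j) X[, j, drop = FALSE])
  names(b) <- colnames(X)
  b
}

test_that("a strong single predictor is selected first with an accurate coefficient", {
  set.seed(101)
  n <- 200
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("x", 1:10)))
  y <- 2 * X[, 5] + rnorm(n, sd = 0.1)
  path <- stepwise_select(y, make_blocks(X),
                          settings = selection_settings(alpha = 0.01))
  expect_equal(path$states[[1]]$block, "x5")
  red <- reduce_by_split_cv(path)
  fit <- lm(y ~ X[, red$selected])
  i5 <- which(red$selected == "x5") + 1
  se <- sqrt(diag(vcov(fit)))[i5]
  expect_lt(abs(coef(fit)[i5] - 2), 3 * se)
})

test_that("pure-noise responses at stringent alpha yield empty selections", {
  set.seed(202)
  empties <- 0L
  for (i in 1:200) {
    n <- 30
    X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("x", 1:10)))
    y <- rnorm(n)
    path <- stepwise_select(y, make_blocks(X),
                            settings = selection_settings(alpha = 1e-6))
    empties <- empties + (length(path$selected) == 0L)
  }
  # expected non-empty rate ~ 10 x 1e-6 per replicate
  expect_gte(empties, 199L)
})

test_that("duplicate candidate columns trigger a collinearity skip, not a crash", {
  set.seed(303)
  n <- 50
  x <- rnorm(n)
  y <- x + rnorm(n, sd = 0.2)
  blocks <- list(a = matrix(x), b = matrix(x), z = matrix(rnorm(n)))
  path <- stepwise_select(y, blocks,
                          settings = selection_settings(alpha = 0.05))
  expect_true(sum(path$selected %in% c("a", "b")) <= 1)
  expect_true(any(grepl("collinear", path$flags)))
})

test_that("every decision matches the brute-force oracle on random instances", {
  set.seed(404)
  for (i in 1:10) {
    n <- 40
    k <- sample(4:8, 1)
    X <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("x", 1:k)))
    beta <- ifelse(runif(k) < 0.4, rnorm(k, sd = 1.5), 0)
    y <- drop(X %*% beta) + rnorm(n)
    alpha <- sample(c(0.01, 0.05, 0.2), 1)
    mine <- stepwise_select(y, make_blocks(X),
                            settings = selection_settings(alpha = alpha))
    orac <- oracle_stepwise(y, make_blocks(X), alpha = alpha)
    expect_identical(decisions_of(mine), decisions_of(orac))
    expect_identical(mine$selected, orac$selected)
  }
})

test_that("training SSE is non-increasing along the forward path", {
  set.seed(505)
  n <- 80
  X <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, paste0("x", 1:12)))
  y <- X[, 1] - X[, 7] + rnorm(n)
  path <- stepwise_select(y, make_blocks(X),
                          settings = selection_settings(alpha = 0.3))
  adds <- Filter(function(s) s$action == "add", path$states)
  sse <- vapply(adds, function(s) {
    sum(resid(lm(y ~ X[, s$selected, drop = FALSE]))^2)
  }, 0)
  expect_true(all(diff(sse) <= 1e-8))
})

test_that("split-sample CV pruning recovers a true one-variable prefix", {
  # hand-built path: prefix 1 is the true model, later steps add pure-noise
  # columns that never saw the response during selection
  set.seed(606)
  hits <- 0L
  for (i in 1:20) {
    n <- 200
    X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("x", 1:5)))
    y <- 1.5 * X[, 1] + rnorm(n)
    blocks <- make_blocks(X)
    states <- lapply(seq_len(5), function(k)
      list(action = "add", block = paste0("x", k),
           p = NA_real_, selected = paste0("x", seq_len(k))))
    path <- structure(list(states = states, selected = names(blocks),
                           flags = character(0), n = n,
                           settings = selection_settings(alpha = 0.3, seed = i),
                           base = matrix(1, n, 1), blocks = blocks, y = y),
                      class = "stepwise_path")
    red <- reduce_by_split_cv(path)
    expect_gte(red$size, 1L)
    expect_equal(red$selected[1], "x1")
    hits <- hits + identical(red$selected, "x1")
  }
  # a noise column survives pruning only when its chance alignment with y
  # also wins the cross-validation (~P(chi-square_1 > ~2) per column)
  expect_gte(hits, 16L)
})

test_that("pruning handles empty paths and breaks ties toward the smaller model", {
  set.seed(707)
  n <- 40
  y <- rnorm(n)
  path <- stepwise_select(y, list(x = matrix(rnorm(n))),
                          settings = selection_settings(alpha = 1e-8))
  red <- reduce_by_split_cv(path)
  expect_equal(red$size, 0L)
  # duplicate-information columns: identical CV error at sizes 1 and 2
  x <- rnorm(n)
  y2 <- x + rnorm(n, sd = 0.1)
  path2 <- stepwise_select(y2, list(a = matrix(x), b = matrix(x)),
                           settings = selection_settings(alpha = 0.9))
  red2 <- reduce_by_split_cv(path2)
  expect_lte(red2$size, 1L)
})

test_that("constant responses produce an empty path", {
  path <- stepwise_select(rep(3, 20), list(x = matrix(rnorm(20))),
                          settings = selection_settings(alpha = 0.5))
  expect_length(path$selected, 0)
  expect_length(path$states, 0)
})

test_that("block order only matters through documented tie-breaks", {
  set.seed(808)
  n <- 60
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("x", 1:6)))
  y <- X[, 2] + 0.5 * X[, 4] + rnorm(n, sd = 0.3)
  b1 <- make_blocks(X)
  b2 <- rev(b1)
  s <- selection_settings(alpha = 0.05)
  p1 <- stepwise_select(y, b1, settings = s)
  p2 <- stepwise_select(y, b2, settings = s)
  expect_setequal(p1$selected, p2$selected)
})
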