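test_that("a noiseless single-QTL family recovers the marker and its effect exactly", {
  sim <- tiny_panel(seed = 31, heritability = 1, founder_polymorphism_rate = 1,
                    n_groups = 1, markers_per_group = 25,
                    qtl = data.frame(chrom = "1", cM = 20, eff1 = 1.3, eff2 = 1.3))
  fit <- fit_sf(sim$panel, sim$phen, "F1", sim$panel$map,
                selection_settings(alpha = 0.01))
  qm <- sim$truth$qtl$marker[1]
  expect_true(qm %in% fit$selected_loci)
  expect_equal(unname(fit$effects[[qm]]["F1"]), 1.3, tolerance = 1e-8)
})

test_that("a sub-map without the QTL selects a linked neighbour with attenuated effect", {
  sim <- tiny_panel(seed = 33, heritability = 0.9, founder_polymorphism_rate = 1,
                    n_families = 1, lines_per_family = 300,
                    n_groups = 1, markers_per_group = 41, spacing_cM = 1,
                    qtl = data.frame(chrom = "1", cM = 20, eff1 = 1.0))
  qm <- sim$truth$qtl$marker[1]
  submap_markers <- setdiff(sim$panel$map$marker, qm)
  sm <- sim$panel$map[sim$panel$map$marker %in% submap_markers, ]
  sm <- linkage_map(sm$marker, sm$chrom, sm$cM, sort = FALSE)
  fit <- fit_sf(sim$panel, sim$phen, "F1", sm, selection_settings(alpha = 0.001))
  expect_gt(length(fit$selected_loci), 0)
  pos <- sim$panel$map$cM[match(fit$selected_loci, sim$panel$map$marker)]
  expect_lte(min(abs(pos - 20)), 5)  # neighbour of the excluded QTL
  betas <- vapply(fit$effects, function(e) unname(e["F1"]), 0)
  expect_lt(max(abs(betas)), 1.05)   # attenuated relative to the true 1.0
})

test_that("an intercept-only SF fit predicts the training-family mean", {
  sim <- tiny_panel(seed = 35)
  lines <- sim$phen$line[sim$phen$family == "F1"]
  fit <- fit_sf(sim$panel, sim$phen, "F1", sim$panel$map,
                selection_settings(alpha = 1e-12), lines = lines[1:40])
  if (length(fit$selected_loci) == 0) {
    p <- predict_qtl(fit, sim$panel, lines[41:50])
    expect_equal(p$predicted,
                 rep(mean(sim$phen$value[match(lines[1:40], sim$phen$line)]), 10))
  }
  fit0 <- structure(list(kind = "SF", family = "F1", submap = sim$panel$map,
                         selected_loci = character(0),
                         intercepts = c(F1 = 5.0), effects = list(),
                         settings = selection_settings(), tested = character(0),
                         flags = character(0), train_lines = lines),
                    class = "qtl_fit")
  p0 <- predict_qtl(fit0, sim$panel, lines[1:7])
  expect_equal(p0$predicted, rep(5.0, 7))
})

test_that("joint-family fits recover a shared QTL effect in every family", {
  qtl <- data.frame(chrom = "1", cM = 24, eff1 = 1, eff2 = 1, eff3 = 1)
  sim <- tiny_panel(seed = 37, n_families = 3, lines_per_family = 100,
                    heritability = 0.9, founder_polymorphism_rate = 1,
                    n_groups = 1, markers_per_group = 25, qtl = qtl)
  fit <- fit_jf(sim$panel, sim$phen, sim$panel$map,
                selection_settings(alpha = 1e-4))
  qm <- sim$truth$qtl$marker[1]
  expect_true(qm %in% fit$selected_loci)
  eff <- fit$effects[[qm]]
  for (f in c("F1", "F2", "F3")) {
    se_rough <- 3 * sqrt(4 / 100)  # conservative 3-SE band at n_f = 100
    expect_lt(abs(eff[f] - 1), se_rough)
  }
})

test_that("a locus segregating in one family stores effects only for that family", {
  set.seed(39)
  n <- 80
  fam <- rep(c("A", "B"), each = n / 2)
  dos <- matrix(0, n, 6, dimnames = list(paste0("l", 1:n), paste0("m", 1:6)))
  dos[fam == "A", ] <- matrix(rbinom(n / 2 * 6, 1, 0.5), n / 2)
  dos[fam == "B", 1:5] <- matrix(rbinom(n / 2 * 5, 1, 0.5), n / 2)
  # m6 segregates only in family A and carries the QTL there
  panel <- manual_panel(dos, fam, spacing_cM = 10)
  y <- 2 * dos[, 6] + rnorm(n, sd = 0.1) + (fam == "B") * 1.5
  phen <- data.frame(line = rownames(dos), family = fam, value = y)
  fit <- fit_jf(panel, phen, panel$map, selection_settings(alpha = 0.001))
  expect_true("m6" %in% fit$selected_loci)
  expect_equal(names(fit$effects[["m6"]]), "A")
  # family-B predictions are unaffected by the locus
  pb <- predict_qtl(fit, panel, rownames(dos)[fam == "B"])
  fit_wo <- fit
  fit_wo$effects[["m6"]]["A"] <- 0
  pb2 <- predict_qtl(fit_wo, panel, rownames(dos)[fam == "B"])
  expect_equal(pb$predicted, pb2$predicted)
})

test_that("JF and SF agree exactly when a locus segregates in a single family", {
  set.seed(41)
  n <- 60
  fam <- rep(c("A", "B"), each = n / 2)
  dos <- matrix(0, n, 3, dimnames = list(paste0("l", 1:n), paste0("m", 1:3)))
  dos[fam == "A", 1] <- rbinom(n / 2, 1, 0.5)
  dos[, 2] <- rbinom(n, 1, 0.5)
  dos[fam == "A", 3] <- rbinom(n / 2, 1, 0.5)
  panel <- manual_panel(dos, fam, spacing_cM = 30)
  y <- numeric(n)
  y[fam == "A"] <- 1 + 2 * dos[fam == "A", 1]
  y[fam == "B"] <- 3 + rnorm(n / 2, sd = 0.3)
  phen <- data.frame(line = rownames(dos), family = fam, value = y)
  s <- selection_settings(alpha = 0.01)
  jf <- fit_jf(panel, phen, panel$map, s)
  sf <- fit_sf(panel, phen, "A", panel$map, s)
  expect_true("m1" %in% jf$selected_loci)
  expect_true("m1" %in% sf$selected_loci)
  # family-A blocks are orthogonal to family-B rows, so the estimates match
  expect_equal(unname(jf$effects[["m1"]]["A"]),
               unname(sf$effects[["m1"]]["A"]), tolerance = 1e-8)
  expect_equal(unname(jf$intercepts["A"]), unname(sf$intercepts["A"]),
               tolerance = 1e-8)
})

test_that("prediction is the documented affine form and validates its inputs", {
  dos <- matrix(c(1, 0, 1, 1), 2, 2,
                dimnames = list(c("a1", "b1"), c("m3", "m4")))
  panel <- manual_panel(dos, c("famA", "famB"), spacing_cM = 5)
  fit <- structure(list(kind = "JF", family = NULL, submap = panel$map,
                        selected_loci = "m3",
                        intercepts = c(famA = 1, famB = 0),
                        effects = list(m3 = c(famA = 2)),
                        settings = selection_settings(),
                        tested = c("m3", "m4"), flags = character(0),
                        train_lines = character(0)),
                   class = "qtl_fit")
  p <- predict_qtl(fit, panel, c("a1", "b1"))
  expect_equal(p$predicted, c(3, 0))  # famA: 1 + 2*1; famB: intercept only
  fit$intercepts <- c(famA = 1)
  expect_error(predict_qtl(fit, panel, c("a1", "b1")), "no intercept")
  fit$intercepts <- c(famA = 1, famB = 0)
  fit$selected_loci <- "m9"
  fit$effects <- list(m9 = c(famA = 1))
  expect_error(predict_qtl(fit, panel, "a1"), "missing genotypes")
})

test_that("training R-squared of the refit model dominates nested sub-models", {
  sim <- tiny_panel(seed = 43, heritability = 0.6)
  fit <- fit_jf(sim$panel, sim$phen, sim$panel$map,
                selection_settings(alpha = 0.01))
  if (length(fit$selected_loci) >= 2) {
    pred_full <- predict_qtl(fit, sim$panel, sim$phen$line)
    sub <- fit
    sub$selected_loci <- fit$selected_loci[1]
    sub$effects <- fit$effects[1]
    pred_sub <- predict_qtl(sub, sim$panel, sim$phen$line)
    sse_full <- sum((sim$phen$value - pred_full$predicted)^2)
    # refit sub-model properly for a fair nested comparison
    refit <- fit_jf(sim$panel, sim$phen,
                    local({m <- sim$panel$map[sim$panel$map$marker %in% fit$selected_loci[1], ]
                           linkage_map(m$marker, m$chrom, m$cM, sort = FALSE)}),
                    selection_settings(alpha = 0.99))
    pred_re <- predict_qtl(refit, sim$panel, sim$phen$line)
    expect_lte(sse_full, sum((sim$phen$value - pred_re$predicted)^2) + 1e-8)
  } else {
    succeed()
  }
})
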