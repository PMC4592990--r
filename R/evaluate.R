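#' Build a stratified cross-validation plan
#'
#' Each repeat draws, per family, a random `train_fraction` of the family's
#' lines (count = `round(fraction * n_f)`) as the training set; the
#' remainder is the test set.  Splits are seeded and reproducible.
#'
#' @param phen phenotype data.frame (`line`, `family`, `value`).
#' @param n_repeats number of repeats (10 is the usual choice; 50 for
#'   ensemble-of-models experiments).
#' @param train_fraction fraction of each family used for training.
#' @param seed integer seed.
#' @return object of class `cv_plan`: list with `splits` (per repeat, lists
#'   `train` and `test`), plus the plan parameters.
#' @export
make_cv_plan <- function(phen, n_repeats = 10, train_fraction = 0.8,
                         seed = 1L) {
  fam_n <- table(phen$family)
  small <- names(fam_n)[fam_n < 5]
  if (length(small)) stop("families with fewer than 5 lines: ",
                          paste(small, collapse = ", "))
  by_fam <- split(phen$line, phen$family)
  splits <- with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) {
      tr <- unlist(lapply(by_fam, function(ids) {
        sample(ids, round(train_fraction * length(ids)))
      }), use.names = FALSE)
      list(train = tr, test = setdiff(phen$line, tr))
    })
  })
  structure(list(splits = splits, n_repeats = n_repeats,
                 train_fraction = train_fraction, seed = seed),
            class = "cv_plan")
}

#' Signed squared Pearson correlation
#'
#' Prediction ability as the proportion of trait variance explained in the
#' validation set: r-squared of observed vs predicted, carrying the sign of
#' the correlation so that anti-predictive models report negative values
#' rather than being inflated by squaring.
#'
#' @param observed,predicted numeric vectors of equal length (>= 3 pairs),
#'   each with nonzero variance.
#' @return sign(r) * r^2, in [-1, 1].
#' @export
prediction_r2 <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 3) stop("need at least 3 pairs")
  if (stats::var(observed) == 0 || stats::var(predicted) == 0) {
    stop("zero variance: correlation undefined")
  }
  r <- stats::cor(observed, predicted)
  sign(r) * r^2
}

#' Within-family prediction R-squared across CV repeats
#'
#' Computes [prediction_r2()] within each family for each repeat's test
#' predictions, averages over repeats per family, and summarizes across
#' families (mean and standard error over family means).  A family whose
#' R-squared is undefined in a repeat (constant predictions, or absent from
#' that repeat's test set) is flagged and excluded from that repeat.
#'
#' @param predictions list of [prediction_set()]s, one per repeat.
#' @param phen phenotype data.frame with the observed values.
#' @return list with `per_family` (family, mean R2 over repeats, n_repeats
#'   used), `mean_r2` (mean over families), `se_r2` (SE over families), and
#'   `cells` (the family x repeat R2 matrix).
#' @export
within_family_r2 <- function(predictions, phen) {
  if (inherits(predictions, "prediction_set")) predictions <- list(predictions)
  fams <- sort(unique(phen$family))
  cells <- matrix(NA_real_, length(fams), length(predictions),
                  dimnames = list(fams, NULL))
  for (r in seq_along(predictions)) {
    p <- predictions[[r]]
    obs <- phen$value[match(p$line, phen$line)]
    for (f in unique(p$family)) {
      i <- p$family == f
      cells[f, r] <- tryCatch(prediction_r2(obs[i], p$predicted[i]),
                              error = function(e) NA_real_)
    }
  }
  fam_mean <- rowMeans(cells, na.rm = TRUE)
  per_family <- data.frame(family = fams, r2 = unname(fam_mean),
                           n_repeats = rowSums(!is.na(cells)),
                           stringsAsFactors = FALSE)
  ok <- is.finite(fam_mean)
  list(per_family = per_family,
       mean_r2 = mean(fam_mean[ok]),
       se_r2 = if (sum(ok) > 1) stats::sd(fam_mean[ok]) / sqrt(sum(ok)) else NA_real_,
       cells = cells)
}

#' Decompose cross-validated prediction error into bias-squared and variance
#'
#' For each line, predictions from all CV repeats whose test set contains it
#' are collected; the mean prediction estimates the expectation over
#' training sets.  The squared deviation of the observed value from that
#' mean is the bias-squared term — confounded with the irreducible error,
#' which cannot be separated without knowing the true genotypic value — and
#' the mean squared deviation of per-repeat predictions around their mean
#' (population, 1/R form) is the prediction variance.  Per line and in
#' aggregate, bias-squared-plus-irreducible + variance equals the mean
#' squared prediction error exactly.
#'
#' The optional outlier guard excludes predicted values outside the global
#' mean prediction plus or minus 100 standard errors of that mean before
#' decomposition, guarding against collinearity blow-ups in individual
#' resamples; excluded predictions are counted, never silently dropped.
#'
#' @param predictions list of [prediction_set()]s, one per CV repeat
#'   (test-set predictions).
#' @param phen phenotype data.frame with observed values.
#' @param outlier_guard apply the 100-SEM exclusion rule (default TRUE).
#' @return object of class `error_decomposition`: list with `per_line`
#'   (line, n_covering, bias2_plus_irreducible, variance, mse), aggregates
#'   `bias2_plus_irreducible`, `variance`, `mse` (means over lines; variance
#'   over lines covered at least twice), and `n_excluded_outliers`.
#' @export
decompose_error <- function(predictions, phen, outlier_guard = TRUE) {
  if (inherits(predictions, "prediction_set")) predictions <- list(predictions)
  all_line <- unlist(lapply(predictions, `[[`, "line"))
  all_pred <- unlist(lapply(predictions, `[[`, "predicted"))
  n_excl <- 0L
  if (outlier_guard && length(all_pred) > 1) {
    m <- mean(all_pred)
    sem <- stats::sd(all_pred) / sqrt(length(all_pred))
    keep <- abs(all_pred - m) <= 100 * sem
    n_excl <- sum(!keep)
    all_line <- all_line[keep]
    all_pred <- all_pred[keep]
  }
  by_line <- split(all_pred, all_line)
  obs <- phen$value[match(names(by_line), phen$line)]
  if (anyNA(obs)) stop("predicted lines without observed values")
  hbar <- vapply(by_line, mean, 0)
  nrep <- vapply(by_line, length, 0L)
  bias2 <- (obs - hbar)^2
  variance <- vapply(by_line, function(h) mean((h - mean(h))^2), 0)
  mse <- mapply(function(h, y) mean((y - h)^2), by_line, obs)
  if (!any(nrep >= 2L)) stop("no line covered by two test sets: variance undefined")
  per_line <- data.frame(line = names(by_line), n_covering = nrep,
                         bias2_plus_irreducible = bias2,
                         variance = variance, mse = mse,
                         stringsAsFactors = FALSE, row.names = NULL)
  structure(list(per_line = per_line,
                 bias2_plus_irreducible = mean(bias2),
                 variance = mean(variance[nrep >= 2L]),
                 mse = mean(mse),
                 n_excluded_outliers = n_excl,
                 n_single_coverage = sum(nrep < 2L)),
            class = "error_decomposition")
}

#' @export
print.error_decomposition <- function(x, ...) {
  cat(sprintf("prediction error: bias2+irreducible = %.4g, variance = %.4g, mse = %.4g (%d outliers excluded)\n",
              x$bias2_plus_irreducible, x$variance, x$mse,
              x$n_excluded_outliers))
  invisible(x)
}

#' Resample model inclusion probability
#'
#' For each marker, the proportion of resampled analyses in which it was
#' tested as a candidate and selected into the model of interest.  The
#' default denominator counts all resamples; the `tested_samples` policy
#' divides by the number of resamples in which the marker was a candidate
#' (markers never tested then report NA).
#'
#' @param records list, one element per resample, each a list with
#'   character vectors `tested` and `selected` (as returned by
#'   [selection_record()]).
#' @param universe character vector of all marker ids under study.
#' @param denominator_policy `"all_samples"` (default) or `"tested_samples"`.
#' @return data.frame of class `rmip_table`: `marker`, `rmip`,
#'   `n_selected`, `n_tested`, `n_samples`.
#' @export
rmip <- function(records, universe,
                 denominator_policy = c("all_samples", "tested_samples")) {
  denominator_policy <- match.arg(denominator_policy)
  R <- length(records)
  unknown <- setdiff(unlist(lapply(records, `[[`, "selected")), universe)
  if (length(unknown)) stop("selected markers outside the universe: ",
                            paste(utils::head(unknown, 5), collapse = ", "))
  n_tested <- n_sel <- stats::setNames(integer(length(universe)), universe)
  for (rec in records) {
    t_in <- intersect(rec$tested, universe)
    s_in <- intersect(intersect(rec$selected, rec$tested), universe)
    n_tested[t_in] <- n_tested[t_in] + 1L
    n_sel[s_in] <- n_sel[s_in] + 1L
  }
  val <- if (denominator_policy == "all_samples") {
    n_sel / R
  } else {
    ifelse(n_tested > 0, n_sel / n_tested, NA_real_)
  }
  structure(data.frame(marker = universe, rmip = unname(val),
                       n_selected = unname(n_sel), n_tested = unname(n_tested),
                       n_samples = R, stringsAsFactors = FALSE),
            class = c("rmip_table", "data.frame"),
            denominator_policy = denominator_policy)
}
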