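#' Combine heterogeneous model predictions with fixed weights
#'
#' Model averaging across predictors of different kinds (TAGGING-assisted
#' QTL ensembles, GBLUP variants, ...): per line, the weighted sum of the
#' component predictions.  Equal weights over two components reproduce the
#' 0.5/0.5 pairing scheme; named presets `"equal"` (1/k each) and
#' `"half_gblup"` (1/4, 1/4, 1/2 — QTL components split one half, the last,
#' GBLUP component takes the other) cover the common three-component cases.
#'
#' @param components list of [prediction_set()]s over identical line sets.
#' @param weights numeric simplex vector (nonnegative, summing to one
#'   within 1e-9), or `"equal"`, or `"half_gblup"`.
#' @param model_label label for the output.
#' @return a [prediction_set()].
#' @export
combine_predictions <- function(components, weights = "equal",
                                model_label = "combined") {
  k <- length(components)
  if (identical(weights, "equal")) {
    weights <- rep(1 / k, k)
  } else if (identical(weights, "half_gblup")) {
    if (k < 2) stop("half_gblup preset needs >= 2 components")
    weights <- c(rep(0.5 / (k - 1), k - 1), 0.5)
  }
  if (any(weights < -1e-12)) stop("weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  aggregate_predictions(components, a0 = 0, weights = weights,
                        model_label = model_label)
}

#' Enumerate all equal-weight model combinations
#'
#' Builds every nonempty subset of the components, each averaged with equal
#' weights over its members — the full-factorial presence/absence layout
#' used to assess each model's contribution to ensemble accuracy (15
#' combinations for four components).
#'
#' @param components named list of [prediction_set()]s (2 to 6 components).
#' @return named list of [prediction_set()]s, one per nonempty subset;
#'   names join member names with `+`.
#' @export
enumerate_factorial <- function(components) {
  k <- length(components)
  if (k < 2 || k > 6) stop("2 to 6 components supported, got ", k)
  if (is.null(names(components))) names(components) <- paste0("M", seq_len(k))
  out <- list()
  for (size in seq_len(k)) {
    for (idx in utils::combn(k, size, simplify = FALSE)) {
      nm <- paste(names(components)[idx], collapse = "+")
      out[[nm]] <- combine_predictions(components[idx], "equal",
                                       model_label = nm)
    }
  }
  out
}

#' Pseudo-optimal ensemble weights by Nelder-Mead
#'
#' Searches the weight simplex for the fixed coefficient vector maximizing
#' the mean within-family prediction R-squared across all CV repeats
#' jointly.  The simplex constraint (nonnegative, sum-to-one) is enforced by
#' optimizing k-1 free logits mapped through a softmax; runs start from each
#' vertex and from seeded random points, and the best result is returned —
#' guaranteed no worse than any single component.  Because the objective
#' uses the *test-set* phenotypes, the result is an idealistic upper bound
#' on ensemble accuracy, not an honest prediction; outputs are labelled
#' accordingly.
#'
#' @param component_sets list over CV repeats; each element a named list of
#'   [prediction_set()]s (the same components in the same order each repeat).
#' @param phen phenotype data.frame with observed values.
#' @param seed seed for the random restarts.
#' @param n_restarts random starts in addition to the vertex starts.
#' @param max_iter Nelder-Mead iteration cap per start.
#' @return list of class `weight_vector`: `weights` (named simplex vector),
#'   `objective` (achieved mean within-family R2), `trace` (objective per
#'   start), and `uses_test_phenotypes = TRUE`.
#' @export
optimize_weights <- function(component_sets, phen, seed = 1L,
                             n_restarts = 3, max_iter = 500) {
  k <- length(component_sets[[1]])
  if (k < 2) stop("need >= 2 components")
  comp_names <- names(component_sets[[1]])
  if (is.null(comp_names)) comp_names <- paste0("M", seq_len(k))
  objective <- function(w) {
    combined <- lapply(component_sets, function(cs)
      aggregate_predictions(cs, a0 = 0, weights = w))
    within_family_r2(combined, phen)$mean_r2
  }
  softmax <- function(z) {
    e <- exp(c(z, 0) - max(c(z, 0)))
    e / sum(e)
  }
  best <- list(value = -Inf, weights = NULL)
  trace <- numeric(0)
  # vertex starts (evaluated both exactly and as optimizer seeds)
  for (v in seq_len(k)) {
    w <- rep(0, k); w[v] <- 1
    val <- objective(w)
    trace <- c(trace, val)
    if (val > best$value) best <- list(value = val, weights = w)
  }
  starts <- c(lapply(seq_len(k), function(v) {
    z <- rep(-10, k - 1); if (v < k) z[v] <- 10; z
  }),
  with_seed(seed, lapply(seq_len(n_restarts),
                         function(i) stats::rnorm(k - 1))))
  for (z0 in starts) {
    opt <- tryCatch(
      # Nelder-Mead also for k = 2 (one free logit); R's advisory about
      # 1-D Nelder-Mead is expected and harmless here
      suppressWarnings(
        stats::optim(z0, function(z) -objective(softmax(z)),
                     method = "Nelder-Mead",
                     control = list(maxit = max_iter, reltol = 1e-8))),
      error = function(e) NULL)
    if (is.null(opt)) next
    w <- softmax(opt$par)
    val <- -opt$value
    trace <- c(trace, val)
    if (val > best$value) best <- list(value = val, weights = w)
  }
  structure(list(weights = stats::setNames(best$weights, comp_names),
                 objective = best$value, trace = trace,
                 uses_test_phenotypes = TRUE),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("pseudo-optimal ensemble weights (tuned on test phenotypes):\n")
  print(round(x$weights, 4))
  cat(sprintf("objective (mean within-family R2): %.4f\n", x$objective))
  invisible(x)
}
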