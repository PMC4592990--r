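#' Fit single-family models for every family on one sub-map
#'
#' The SF base learner of an ESF ensemble is a collection of per-family
#' stepwise fits sharing one sub-map; prediction dispatches each line to its
#' family's fit.  Families whose fit fails (e.g. no segregating markers)
#' fall back to an intercept-only model at the training-family mean.
#'
#' @inheritParams fit_jf
#' @return object of class `sf_set` holding one `qtl_fit` per family.
#' @export
fit_sf_all <- function(panel, phen, submap, settings = selection_settings(),
                       lines = NULL) {
  if (is.null(lines)) lines <- panel$line_ids
  fam_ids <- sort(unique(panel$family[lines]))
  fits <- lapply(fam_ids, function(f) {
    fl <- lines[panel$family[lines] == f]
    tryCatch(fit_sf(panel, phen, f, submap, settings, lines = fl),
             error = function(e) .intercept_only_sf(phen, fl, f, submap, settings))
  })
  names(fits) <- fam_ids
  structure(list(fits = fits, submap = submap, settings = settings,
                 train_lines = lines),
            class = "sf_set")
}

.intercept_only_sf <- function(phen, lines, family, submap, settings) {
  y <- .phen_lookup(phen, lines)
  structure(list(kind = "SF", family = family, submap = submap,
                 selected_loci = character(0),
                 intercepts = stats::setNames(mean(y), family),
                 effects = list(), settings = settings,
                 tested = character(0), flags = "fit-failed:intercept-only",
                 train_lines = lines),
            class = "qtl_fit")
}

#' @export
selection_record.sf_set <- function(fit) {
  recs <- lapply(fit$fits, selection_record)
  list(tested = unique(unlist(lapply(recs, `[[`, "tested"))),
       selected = unique(unlist(lapply(recs, `[[`, "selected"))))
}

.predict_base <- function(fit, panel, line_ids, label, test_set_id) {
  if (inherits(fit, "sf_set")) {
    fam <- panel$family[line_ids]
    unknown <- setdiff(unique(fam), names(fit$fits))
    if (length(unknown)) stop("no SF fit for family: ",
                              paste(unknown, collapse = ", "))
    preds <- lapply(names(fit$fits), function(f) {
      ids <- line_ids[fam == f]
      if (!length(ids)) return(NULL)
      predict_qtl(fit$fits[[f]], panel, ids, model_label = label,
                  test_set_id = test_set_id)
    })
    out <- do.call(rbind, preds)
    out <- out[match(line_ids, out$line), , drop = FALSE]
    rownames(out) <- NULL
    structure(out, class = c("prediction_set", "data.frame"),
              model_label = label, test_set_id = test_set_id)
  } else {
    predict_qtl(fit, panel, line_ids, model_label = label,
                test_set_id = test_set_id)
  }
}

#' Fit a TAGGING ensemble (EJF or ESF)
#'
#' Fits one base learner per thinned sub-map, all on the identical training
#' line set: joint-family models for `base_kind = "JF"` (the EJF ensemble)
#' or per-family single-family model collections for `"SF"` (ESF).  Base
#' learners are independent — zero memory, order-invariant, parallelizable.
#' A base learner that fails outright is replaced by an intercept-only fit
#' so the ensemble remains an arithmetic mean over all S sub-maps; if every
#' base fails, fitting errors.
#'
#' @param panel a `genotype_panel`.
#' @param phen phenotype data.frame.
#' @param train_lines training line ids.
#' @param thinned a `thinned_map_set` from [thin_map()].
#' @param base_kind `"JF"` or `"SF"`.
#' @param settings a [selection_settings()].
#' @return object of class `ensemble_fit` with elements `base_fits`, `spec`
#'   (kind, s, default coefficients a0 = 0 and a_s = 1/S), and `status`.
#' @export
fit_tagging <- function(panel, phen, train_lines, thinned,
                        base_kind = c("JF", "SF"),
                        settings = selection_settings()) {
  base_kind <- match.arg(base_kind)
  stopifnot(inherits(thinned, "thinned_map_set"))
  S <- thinned$s
  status <- character(S)
  base_fits <- vector("list", S)
  for (s in seq_len(S)) {
    sm <- thinned$submaps[[s]]
    res <- tryCatch({
      f <- if (base_kind == "JF") {
        fit_jf(panel, phen, sm, settings, lines = train_lines)
      } else {
        fit_sf_all(panel, phen, sm, settings, lines = train_lines)
      }
      list(fit = f, status = "ok")
    }, error = function(e) list(fit = NULL, status = conditionMessage(e)))
    if (is.null(res$fit)) {
      res$fit <- .intercept_only_base(base_kind, panel, phen, train_lines,
                                      sm, settings)
      status[s] <- paste0("intercept-only: ", res$status)
    } else {
      status[s] <- res$status
    }
    base_fits[[s]] <- res$fit
  }
  if (all(startsWith(status, "intercept-only"))) {
    stop("all base learners failed")
  }
  structure(list(base_fits = base_fits,
                 spec = list(base_kind = base_kind, ensemble = "tagging",
                             s = S, a0 = 0, weights = rep(1 / S, S),
                             settings = settings),
                 status = status, train_lines = train_lines),
            class = "ensemble_fit")
}

.intercept_only_base <- function(base_kind, panel, phen, lines, submap, settings) {
  fam_ids <- sort(unique(panel$family[lines]))
  if (base_kind == "SF") {
    fits <- lapply(fam_ids, function(f)
      .intercept_only_sf(phen, lines[panel$family[lines] == f], f, submap, settings))
    names(fits) <- fam_ids
    structure(list(fits = fits, submap = submap, settings = settings,
                   train_lines = lines), class = "sf_set")
  } else {
    y <- .phen_lookup(phen, lines)
    fam <- panel$family[lines]
    structure(list(kind = "JF", family = NULL, submap = submap,
                   selected_loci = character(0),
                   intercepts = vapply(fam_ids, function(f) mean(y[fam == f]), 0),
                   effects = list(), settings = settings,
                   tested = character(0), flags = "fit-failed:intercept-only",
                   train_lines = lines),
              class = "qtl_fit")
  }
}

#' Fit a subagging (subsample aggregating) ensemble
#'
#' The comparator ensemble: instead of thinning markers, each base learner
#' uses the full map on a without-replacement subsample of training lines,
#' drawn stratified within family (80% of each family by default), and
#' predictions are averaged with equal weights.
#'
#' @inheritParams fit_tagging
#' @param map the full `linkage_map` used by every base learner.
#' @param n_subsamples number of subsamples (base learners).
#' @param subsample_fraction within-family fraction drawn per subsample.
#' @param seed seed for the subsample draws.
#' @return an `ensemble_fit`.
#' @export
fit_subagging <- function(panel, phen, train_lines, map,
                          base_kind = c("JF", "SF"),
                          settings = selection_settings(),
                          n_subsamples = 10, subsample_fraction = 0.8,
                          seed = 1L) {
  base_kind <- match.arg(base_kind)
  fam <- panel$family[train_lines]
  sub_lines <- with_seed(seed, {
    lapply(seq_len(n_subsamples), function(i) {
      unlist(lapply(split(train_lines, fam), function(ids) {
        k <- max(1L, round(subsample_fraction * length(ids)))
        if (k >= length(ids)) ids else sample(ids, k)
      }), use.names = FALSE)
    })
  })
  status <- character(n_subsamples)
  base_fits <- vector("list", n_subsamples)
  for (i in seq_len(n_subsamples)) {
    res <- tryCatch({
      f <- if (base_kind == "JF") {
        fit_jf(panel, phen, map, settings, lines = sub_lines[[i]])
      } else {
        fit_sf_all(panel, phen, map, settings, lines = sub_lines[[i]])
      }
      list(fit = f, status = "ok")
    }, error = function(e) list(fit = NULL, status = conditionMessage(e)))
    if (is.null(res$fit)) {
      res$fit <- .intercept_only_base(base_kind, panel, phen, sub_lines[[i]],
                                      map, settings)
      status[i] <- paste0("intercept-only: ", res$status)
    } else {
      status[i] <- res$status
    }
    base_fits[[i]] <- res$fit
  }
  structure(list(base_fits = base_fits,
                 spec = list(base_kind = base_kind, ensemble = "subagging",
                             s = n_subsamples, a0 = 0,
                             weights = rep(1 / n_subsamples, n_subsamples),
                             settings = settings,
                             subsample_fraction = subsample_fraction),
                 status = status, train_lines = train_lines),
            class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf("%s ensemble of %d %s base learners\n",
              x$spec$ensemble, x$spec$s, x$spec$base_kind))
  invisible(x)
}

#' @export
selection_record.ensemble_fit <- function(fit) {
  recs <- lapply(fit$base_fits, selection_record)
  list(tested = unique(unlist(lapply(recs, `[[`, "tested"))),
       selected = unique(unlist(lapply(recs, `[[`, "selected"))))
}

#' Predict from an ensemble fit
#'
#' Evaluates every base learner on the test lines and returns the affine
#' combination a0 + sum of weights x base predictions (with the default
#' coefficients, the arithmetic mean over base learners).
#'
#' @param efit an `ensemble_fit`.
#' @param panel a `genotype_panel`.
#' @param line_ids test line ids.
#' @param model_label,test_set_id labels for the output.
#' @return a [prediction_set()].
#' @export
predict_ensemble <- function(efit, panel, line_ids,
                             model_label = paste0("E", efit$spec$base_kind),
                             test_set_id = "test") {
  preds <- lapply(efit$base_fits, .predict_base, panel = panel,
                  line_ids = line_ids, label = model_label,
                  test_set_id = test_set_id)
  aggregate_predictions(preds, a0 = efit$spec$a0,
                        weights = efit$spec$weights,
                        model_label = model_label,
                        test_set_id = test_set_id)
}

#' Aggregate base-learner predictions
#'
#' The ensemble estimator: per line, a0 + sum of weights_s x prediction_s.
#' With the default a0 = 0 and equal weights 1/S this is the arithmetic
#' mean of the base learners.  All sets must cover the identical line set.
#'
#' @param predictions list of [prediction_set()]s over the same lines.
#' @param a0 additive constant (default 0).
#' @param weights numeric vector, one per prediction set (default 1/S each).
#' @param model_label,test_set_id labels for the output.
#' @return a [prediction_set()] in the line order of the first input.
#' @export
aggregate_predictions <- function(predictions, a0 = 0, weights = NULL,
                                  model_label = "ensemble",
                                  test_set_id = NULL) {
  S <- length(predictions)
  if (!S) stop("no predictions to aggregate")
  if (is.null(weights)) weights <- rep(1 / S, S)
  if (length(weights) != S) stop("need one weight per prediction set")
  ref <- predictions[[1]]
  for (p in predictions[-1]) {
    extra <- setdiff(p$line, ref$line)
    miss <- setdiff(ref$line, p$line)
    if (length(extra) || length(miss)) {
      stop("mismatched line sets; missing: ",
           paste(utils::head(miss, 5), collapse = ", "),
           "; extra: ", paste(utils::head(extra, 5), collapse = ", "))
    }
  }
  P <- vapply(seq_len(S), function(s) {
    p <- predictions[[s]]
    weights[s] * p$predicted[match(ref$line, p$line)]
  }, numeric(nrow(ref)))
  P <- matrix(P, nrow = nrow(ref))
  # summing each row in sorted order makes the result invariant to the
  # ordering of the base learners, bit for bit
  acc <- a0 + apply(P, 1, function(v) sum(sort(v)))
  if (is.null(test_set_id)) test_set_id <- attr(ref, "test_set_id")
  prediction_set(ref$line, ref$family, acc,
                 model_label = model_label, test_set_id = test_set_id)
}
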