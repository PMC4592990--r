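#' Model-grid cross-validation driver
#'
#' Runs a grid of prediction models through a common stratified
#' cross-validation: per repeat, every requested model is fitted on the
#' training lines and evaluated on the held-out lines, then within-family
#' R-squared, the bias/variance decomposition, and (for QTL-based models)
#' RMIP are computed from the pooled predictions.  A model cell that errors
#' is recorded and skipped; the rest of the grid completes.
#'
#' @param panel a `genotype_panel`.
#' @param phen phenotype data.frame.
#' @param models named list of model specs, each a list with `kind` (one of
#'   `"SF"`, `"JF"`, `"ESF"`, `"EJF"`, `"SUBSF"`, `"SUBJF"`, `"SGBLUP"`,
#'   `"JGBLUP"`, `"HGBLUP"`) plus kind-specific fields: `alpha` (QTL
#'   models), `s` (thinning factor for ESF/EJF), `n_subsamples` and
#'   `subsample_fraction` (subagging), `G` (a `gmatrix`, required for
#'   HGBLUP, optional override elsewhere).
#' @param cv list with `n_repeats`, `train_fraction`, `seed` for
#'   [make_cv_plan()].
#' @param decompose also run [decompose_error()] per model (needs a line to
#'   fall in two test sets, i.e. `n_repeats >= 2`).
#' @return list with `summary` (one row per model: mean and SE of
#'   within-family R2), `per_model` (predictions, R2 detail, optional
#'   decomposition and selection records), and the `cv_plan`.
#' @export
run_experiment <- function(panel, phen, models,
                           cv = list(n_repeats = 10, train_fraction = 0.8,
                                     seed = 1L),
                           decompose = TRUE) {
  plan <- make_cv_plan(phen, cv$n_repeats, cv$train_fraction, cv$seed)
  if (is.null(names(models))) {
    names(models) <- vapply(models, function(m) m$kind, "")
  }
  # G matrices shared across repeats
  need_sg <- any(vapply(models, function(m) m$kind == "SGBLUP", NA))
  need_jg <- any(vapply(models, function(m)
    m$kind == "JGBLUP" && is.null(m$G), NA))
  G_by_family <- NULL
  if (need_sg) {
    fams <- sort(unique(panel$family))
    G_by_family <- lapply(fams, function(f) {
      ids <- panel$line_ids[panel$family == f]
      vanraden1_g(panel$dosage[ids, , drop = FALSE])
    })
    names(G_by_family) <- fams
  }
  G_panel <- if (need_jg) vanraden1_g(panel$dosage) else NULL

  per_model <- lapply(models, function(m)
    list(predictions = list(), records = list(), errors = character(0)))
  for (r in seq_along(plan$splits)) {
    sp <- plan$splits[[r]]
    for (nm in names(models)) {
      m <- models[[nm]]
      res <- tryCatch(
        .fit_predict_one(m, panel, phen, sp$train, sp$test, r,
                         G_by_family, G_panel, nm),
        error = function(e) {
          list(error = sprintf("repeat %d: %s", r, conditionMessage(e)))
        })
      if (!is.null(res$error)) {
        per_model[[nm]]$errors <- c(per_model[[nm]]$errors, res$error)
      } else {
        per_model[[nm]]$predictions[[r]] <- res$pred
        if (!is.null(res$record)) per_model[[nm]]$records[[r]] <- res$record
      }
    }
  }
  for (nm in names(models)) {
    pm <- per_model[[nm]]
    preds <- Filter(Negate(is.null), pm$predictions)
    if (length(preds)) {
      per_model[[nm]]$r2 <- within_family_r2(preds, phen)
      if (decompose && length(preds) >= 2) {
        per_model[[nm]]$decomposition <-
          tryCatch(decompose_error(preds, phen), error = function(e) NULL)
      }
    }
  }
  summary <- do.call(rbind, lapply(names(models), function(nm) {
    r2 <- per_model[[nm]]$r2
    data.frame(model = nm,
               kind = models[[nm]]$kind,
               mean_r2 = if (is.null(r2)) NA_real_ else r2$mean_r2,
               se_r2 = if (is.null(r2)) NA_real_ else r2$se_r2,
               n_errors = length(per_model[[nm]]$errors),
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, per_model = per_model, cv_plan = plan)
}

.fit_predict_one <- function(m, panel, phen, train, test, r,
                             G_by_family, G_panel, label) {
  settings <- selection_settings(alpha = if (is.null(m$alpha)) 0.01 else m$alpha,
                                 seed = r)
  kind <- m$kind
  if (kind %in% c("ESF", "EJF")) {
    thinned <- thin_map(panel$map, m$s)
    fit <- fit_tagging(panel, phen, train, thinned,
                       base_kind = if (kind == "EJF") "JF" else "SF",
                       settings = settings)
    pred <- predict_ensemble(fit, panel, test, model_label = label,
                             test_set_id = r)
    return(list(pred = pred, record = selection_record(fit)))
  }
  if (kind %in% c("SUBSF", "SUBJF")) {
    fit <- fit_subagging(panel, phen, train, panel$map,
                         base_kind = if (kind == "SUBJF") "JF" else "SF",
                         settings = settings,
                         n_subsamples = if (is.null(m$n_subsamples)) 10 else m$n_subsamples,
                         subsample_fraction = if (is.null(m$subsample_fraction)) 0.8 else m$subsample_fraction,
                         seed = r)
    pred <- predict_ensemble(fit, panel, test, model_label = label,
                             test_set_id = r)
    return(list(pred = pred, record = selection_record(fit)))
  }
  if (kind == "JF") {
    fit <- fit_jf(panel, phen, panel$map, settings, lines = train)
    return(list(pred = predict_qtl(fit, panel, test, model_label = label,
                                   test_set_id = r),
                record = selection_record(fit)))
  }
  if (kind == "SF") {
    fit <- fit_sf_all(panel, phen, panel$map, settings, lines = train)
    return(list(pred = .predict_base(fit, panel, test, label, r),
                record = selection_record(fit)))
  }
  if (kind == "SGBLUP") {
    fams <- sort(unique(panel$family[test]))
    preds <- lapply(fams, function(f) {
      tr <- train[panel$family[train] == f]
      te <- test[panel$family[test] == f]
      fit <- fit_gblup(G_by_family[[f]], phen, tr, "grand_mean")
      predict_gblup(fit, G_by_family[[f]], te, phen, model_label = label,
                    test_set_id = r)
    })
    out <- do.call(rbind, preds)
    out <- out[match(test, out$line), , drop = FALSE]
    rownames(out) <- NULL
    return(list(pred = structure(out,
                                 class = c("prediction_set", "data.frame"),
                                 model_label = label, test_set_id = r)))
  }
  if (kind %in% c("JGBLUP", "HGBLUP")) {
    G <- if (!is.null(m$G)) m$G else G_panel
    if (is.null(G)) stop(kind, " requires a G matrix")
    fit <- fit_gblup(G, phen, train, "family_means")
    return(list(pred = predict_gblup(fit, G, test, phen, model_label = label,
                                     test_set_id = r)))
  }
  stop("unknown model kind: ", kind)
}
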