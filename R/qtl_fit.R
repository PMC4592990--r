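#' @title Single-family and joint-family stepwise QTL models
#' @description Base learners of the TAGGING framework: multiple linear
#'   regression with stepwise marker selection at a predefined alpha,
#'   followed by split-sample CV pruning, then an OLS refit on the retained
#'   loci.  The single-family (SF) model fits one family with one additive
#'   effect per selected marker; the joint-family (JF) model fits all
#'   families together with per-family intercepts and family-specific allele
#'   effects at each selected locus (a locus enters and leaves as one block
#'   of its segregating families' columns, tested by a joint partial F).
#' @name qtl_models
NULL

.phen_lookup <- function(phen, lines) {
  i <- match(lines, phen$line)
  if (anyNA(i)) stop("lines without phenotypes: ",
                     paste(utils::head(lines[is.na(i)], 5), collapse = ", "))
  phen$value[i]
}

.segregating <- function(dosage_sub) {
  apply(dosage_sub, 2, function(v) max(v) - min(v) > 0)
}

#' Fit a single-family stepwise QTL model
#'
#' Candidates are the sub-map markers that segregate among the training
#' lines of the family; each is a single design column of non-reference
#' allele dosage, so effects read as additive substitution effects relative
#' to the reference parent.  With no segregating markers (or none surviving
#' selection) the fit degenerates to intercept-only and predicts the
#' training-family mean — that is a valid base learner, not an error.
#'
#' @param panel a `genotype_panel`.
#' @param phen phenotype data.frame (`line`, `family`, `value`).
#' @param family the family id to fit.
#' @param submap the `linkage_map` defining the candidate markers.
#' @param settings a [selection_settings()].
#' @param lines training line ids (default: all lines of the family).
#' @return object of class `qtl_fit` with the selected loci, intercept,
#'   per-locus effects, and the tested candidate set (for RMIP).
#' @export
fit_sf <- function(panel, phen, family, submap,
                   settings = selection_settings(), lines = NULL) {
  if (is.null(lines)) lines <- panel$line_ids[panel$family == family]
  lines <- lines[panel$family[lines] == family]
  if (!length(lines)) stop("no training lines in family ", family)
  y <- .phen_lookup(phen, lines)
  mk <- intersect(submap$marker, colnames(panel$dosage))
  if (length(mk) < length(submap$marker)) {
    stop("sub-map markers missing from the panel: ",
         paste(utils::head(setdiff(submap$marker, mk), 5), collapse = ", "))
  }
  D <- panel$dosage[lines, submap$marker, drop = FALSE]
  seg <- .segregating(D)
  tested <- submap$marker[seg]
  blocks <- lapply(tested, function(m) D[, m, drop = FALSE])
  names(blocks) <- tested
  path <- stepwise_select(y, blocks, base = NULL, settings = settings)
  red <- reduce_by_split_cv(path)
  sel <- red$selected
  if (length(sel)) {
    X <- cbind(`(Intercept)` = 1, D[, sel, drop = FALSE])
    cf <- stats::lm.fit(X, y)$coefficients
    cf[is.na(cf)] <- 0
    intercept <- unname(cf[1])
    effects <- lapply(sel, function(m) stats::setNames(unname(cf[m]), family))
    names(effects) <- sel
  } else {
    intercept <- mean(y)
    effects <- list()
  }
  structure(list(kind = "SF", family = family, submap = submap,
                 selected_loci = sel,
                 intercepts = stats::setNames(intercept, family),
                 effects = effects, settings = settings,
                 tested = tested, flags = path$flags,
                 train_lines = lines),
            class = "qtl_fit")
}

#' Fit a joint-family stepwise QTL model
#'
#' The design always contains one intercept per family (incidence matrix A).
#' Each candidate locus contributes a block of family-specific columns,
#' dosage x family indicator, restricted to the families in which the locus
#' segregates among training lines; the block is tested by a joint partial F
#' over all its columns.  Loci monomorphic panel-wide are never candidates.
#'
#' @inheritParams fit_sf
#' @param lines training line ids (default: all panel lines); at least two
#'   families must be represented.
#' @return object of class `qtl_fit` with per-family intercepts and, per
#'   selected locus, a named vector of family-specific effects (entries only
#'   for families where the locus segregates in training).
#' @export
fit_jf <- function(panel, phen, submap, settings = selection_settings(),
                   lines = NULL) {
  if (is.null(lines)) lines <- panel$line_ids
  fam <- panel$family[lines]
  fam_ids <- sort(unique(fam))
  if (length(fam_ids) < 2L) stop("joint-family model needs >= 2 families")
  y <- .phen_lookup(phen, lines)
  mk_missing <- setdiff(submap$marker, colnames(panel$dosage))
  if (length(mk_missing)) {
    stop("sub-map markers missing from the panel: ",
         paste(utils::head(mk_missing, 5), collapse = ", "))
  }
  D <- panel$dosage[lines, submap$marker, drop = FALSE]
  A <- sapply(fam_ids, function(f) as.numeric(fam == f))
  colnames(A) <- fam_ids

  # per family, which markers segregate among its training lines
  seg_by_fam <- lapply(fam_ids, function(f) .segregating(D[fam == f, , drop = FALSE]))
  names(seg_by_fam) <- fam_ids
  blocks <- list()
  for (j in seq_along(submap$marker)) {
    m <- submap$marker[j]
    segf <- fam_ids[vapply(fam_ids, function(f) seg_by_fam[[f]][j], NA)]
    if (!length(segf)) next
    cols <- D[, m] * A[, segf, drop = FALSE]
    colnames(cols) <- paste(m, segf, sep = "::")
    blocks[[m]] <- cols
  }
  tested <- names(blocks)
  path <- stepwise_select(y, blocks, base = A, settings = settings)
  red <- reduce_by_split_cv(path)
  sel <- red$selected
  if (length(sel)) {
    X <- cbind(A, do.call(cbind, blocks[sel]))
    cf <- stats::lm.fit(X, y)$coefficients
    cf[is.na(cf)] <- 0
    intercepts <- cf[fam_ids]
    effects <- lapply(sel, function(m) {
      nm <- colnames(blocks[[m]])
      stats::setNames(unname(cf[nm]), sub("^.*::", "", nm))
    })
    names(effects) <- sel
  } else {
    intercepts <- vapply(fam_ids, function(f) mean(y[fam == f]), 0)
    effects <- list()
  }
  structure(list(kind = "JF", family = NULL, submap = submap,
                 selected_loci = sel, intercepts = intercepts,
                 effects = effects, settings = settings,
                 tested = tested, flags = path$flags,
                 train_lines = lines),
            class = "qtl_fit")
}

#' @export
print.qtl_fit <- function(x, ...) {
  cat(sprintf("%s QTL fit%s: %d selected of %d tested markers\n",
              x$kind, if (!is.null(x$family)) paste0(" (family ", x$family, ")") else "",
              length(x$selected_loci), length(x$tested)))
  invisible(x)
}

#' Construct a prediction set
#'
#' The unit that every ensemble averages: one predicted value per test line,
#' tagged with its family and the model that produced it.
#'
#' @param line line ids.
#' @param family family ids (same length).
#' @param predicted finite numeric predictions.
#' @param model_label free-text model name.
#' @param test_set_id identifier of the test split (e.g. a CV repeat).
#' @return data.frame of class `prediction_set`.
#' @export
prediction_set <- function(line, family, predicted,
                           model_label = "model", test_set_id = "test") {
  if (any(!is.finite(predicted))) stop("non-finite predictions")
  structure(data.frame(line = line, family = family, predicted = predicted,
                       stringsAsFactors = FALSE),
            class = c("prediction_set", "data.frame"),
            model_label = model_label, test_set_id = test_set_id)
}

#' Predict lines from a fitted QTL model
#'
#' Computes intercept(family) + sum over selected loci of effect x dosage.
#' For JF fits, a locus contributes nothing to families for which it carries
#' no stored effect (it did not segregate in training, so its column was
#' absorbed by the family intercept).
#'
#' @param fit a `qtl_fit`.
#' @param panel a `genotype_panel` holding the lines' genotypes.
#' @param line_ids lines to predict.
#' @param model_label,test_set_id labels for the returned set.
#' @return a [prediction_set()].
#' @export
predict_qtl <- function(fit, panel, line_ids,
                        model_label = fit$kind, test_set_id = "test") {
  fam <- panel$family[line_ids]
  if (anyNA(fam)) stop("unknown lines: ",
                       paste(utils::head(line_ids[is.na(fam)], 5), collapse = ", "))
  unknown <- setdiff(unique(fam), names(fit$intercepts))
  if (length(unknown)) stop("no intercept for family: ",
                            paste(unknown, collapse = ", "))
  miss <- setdiff(fit$selected_loci, colnames(panel$dosage))
  if (length(miss)) stop("missing genotypes at selected loci: ",
                         paste(miss, collapse = ", "))
  pred <- unname(fit$intercepts[fam])
  for (m in fit$selected_loci) {
    eff <- fit$effects[[m]]
    b <- eff[fam]
    b[is.na(b)] <- 0
    pred <- pred + panel$dosage[line_ids, m] * unname(b)
  }
  prediction_set(line_ids, unname(fam), unname(pred),
                 model_label = model_label, test_set_id = test_set_id)
}

#' Markers tested and selected by a fit
#'
#' Extracts the resampling record used for RMIP: the candidate (tested)
#' marker set and the selected set.  For ensemble fits a marker counts as
#' selected if any base learner selected it, and as tested if any base
#' learner tested it.
#'
#' @param fit a `qtl_fit`, `sf_set`, or `ensemble_fit`.
#' @return list with character vectors `tested` and `selected`.
#' @export
selection_record <- function(fit) UseMethod("selection_record")

#' @export
selection_record.qtl_fit <- function(fit) {
  list(tested = fit$tested, selected = fit$selected_loci)
}
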