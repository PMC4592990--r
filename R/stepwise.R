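#' Settings for stepwise QTL model selection
#'
#' Entry and stay decisions use a single significance threshold `alpha`
#' applied to the partial-F p-value of each candidate design block, mirroring
#' stepwise multiple regression with one predefined threshold.  After forward
#' selection saturates, the model is pruned by split-sample cross-validation
#' within the training set ([reduce_by_split_cv()]).
#'
#' @param alpha entry/stay p-value threshold in (0, 1).
#' @param max_steps cap on selection steps; guards relaxed-alpha runs on
#'   dense maps.
#' @param reduction_folds folds of the within-training split-sample CV.
#' @param collinearity_tol relative tolerance below which a candidate's
#'   residual design is treated as rank-deficient and skipped.
#' @param seed seed for the deterministic fold striping in the reduction CV.
#' @return list of class `selection_settings`.
#' @export
selection_settings <- function(alpha = 0.01, max_steps = 200,
                               reduction_folds = 5,
                               collinearity_tol = 1e-7, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(alpha = alpha, max_steps = as.integer(max_steps),
                 reduction_folds = as.integer(reduction_folds),
                 collinearity_tol = collinearity_tol, seed = as.integer(seed)),
            class = "selection_settings")
}

#' Forward-backward stepwise selection over design blocks
#'
#' Greedy selection over named candidate blocks (a block is one or more
#' design columns entering and leaving together; single-family models use
#' one column per marker, joint-family models one column per segregating
#' family per marker).  Each forward step adds the block with the smallest
#' partial-F p-value if it is below `alpha`; after every addition any
#' previously included block whose partial-F p-value has risen to `alpha` or
#' above is removed (worst first).  Selection stops when no candidate
#' enters or `max_steps` is reached.  The full step path is returned so the
#' split-sample reduction can revisit every intermediate model.
#'
#' Candidates whose columns are (numerically) linear combinations of the
#' current design are skipped and flagged rather than entered; a block that
#' is only partially collinear is tested on its effective rank.  Ties in
#' p-value resolve to the first candidate in block order, so callers should
#' order blocks by map position.
#'
#' @param y numeric response vector.
#' @param blocks named list of numeric matrices (n x q) or vectors.
#' @param base always-included design (default: intercept column).
#' @param settings a [selection_settings()].
#' @return object of class `stepwise_path`: list with `states` (one entry
#'   per step: action, block, selected-set snapshot, p-value), `selected`
#'   (final set), `flags` (collinearity skips), `n`, and `settings`.
#' @export
stepwise_select <- function(y, blocks, base = NULL, settings = selection_settings()) {
  n <- length(y)
  if (is.null(base)) base <- matrix(1, n, 1)
  base <- as.matrix(base)
  blocks <- lapply(blocks, function(b) as.matrix(b))
  if (is.null(names(blocks)) && length(blocks)) stop("blocks must be named")
  states <- list()
  flags <- character(0)
  sel <- character(0)
  if (stats::var(y) == 0 || length(blocks) == 0L) {
    return(structure(list(states = states, selected = sel, flags = flags,
                          n = n, settings = settings, base = base,
                          blocks = blocks, y = y),
                     class = "stepwise_path"))
  }
  # one flat candidate matrix, subset per step
  Ball <- do.call(cbind, blocks)
  bidx <- split(seq_len(ncol(Ball)), rep(seq_along(blocks),
                                         vapply(blocks, ncol, 0L)))
  names(bidx) <- names(blocks)
  tol <- settings$collinearity_tol

  fit_rss <- function(sel_now) {
    X <- if (length(sel_now)) cbind(base, Ball[, unlist(bidx[sel_now]), drop = FALSE])
         else base
    qx <- qr(X, tol = tol)
    r <- qr.resid(qx, y)
    list(qr = qx, r = r, rss = sum(r^2), rank = qx$rank)
  }

  steps <- 0L
  repeat {
    if (steps >= settings$max_steps) break
    cur <- fit_rss(sel)
    cands <- setdiff(names(blocks), sel)
    if (!length(cands)) break
    Bres <- qr.resid(cur$qr, Ball[, unlist(bidx[cands]), drop = FALSE])
    # column offsets of each candidate inside Bres
    widths <- vapply(bidx[cands], length, 0L)
    off <- cumsum(c(0L, widths[-length(widths)]))
    scale_ref <- sqrt(colSums(Ball[, unlist(bidx[cands]), drop = FALSE]^2))
    pvals <- rep(NA_real_, length(cands))
    for (i in seq_along(cands)) {
      cols <- off[i] + seq_len(widths[i])
      Bi <- Bres[, cols, drop = FALSE]
      qb <- qr(Bi, tol = tol)
      q_eff <- qb$rank
      # treat residual columns with negligible norm as fully explained
      if (q_eff > 0) {
        keep <- sqrt(colSums(Bi^2)) > tol * pmax(scale_ref[cols], 1)
        if (!any(keep)) q_eff <- 0L
      }
      if (q_eff == 0L) {
        flags <- c(flags, paste0("collinear: ", cands[i]))
        next
      }
      df_res <- n - cur$rank - q_eff
      if (df_res <= 0L) {
        flags <- c(flags, paste0("df-exhausted: ", cands[i]))
        next
      }
      qt <- qr.qty(qb, cur$r)
      red <- sum(qt[seq_len(q_eff)]^2)
      rss1 <- max(cur$rss - red, 0)
      if (rss1 <= .Machine$double.eps * max(cur$rss, 1)) {
        pvals[i] <- 0
      } else {
        Fst <- (red / q_eff) / (rss1 / df_res)
        pvals[i] <- stats::pf(Fst, q_eff, df_res, lower.tail = FALSE)
      }
    }
    if (all(is.na(pvals))) break
    best <- which.min(pvals)
    if (!(pvals[best] < settings$alpha)) break
    sel <- c(sel, cands[best])
    steps <- steps + 1L
    states[[length(states) + 1L]] <- list(action = "add",
                                          block = cands[best],
                                          p = pvals[best], selected = sel)
    # backward sweep: drop worst block at/above alpha, repeat
    repeat {
      if (length(sel) < 2L) break
      full <- fit_rss(sel)
      pv <- vapply(sel, function(b) {
        red_fit <- fit_rss(setdiff(sel, b))
        q_eff <- full$rank - red_fit$rank
        df_res <- n - full$rank
        if (q_eff <= 0L || df_res <= 0L) return(1)
        red <- red_fit$rss - full$rss
        if (full$rss <= .Machine$double.eps * max(red_fit$rss, 1)) return(0)
        stats::pf((red / q_eff) / (full$rss / df_res), q_eff, df_res,
                  lower.tail = FALSE)
      }, 0)
      worst <- which.max(pv)
      if (pv[worst] < settings$alpha) break
      dropped <- sel[worst]
      sel <- setdiff(sel, dropped)
      steps <- steps + 1L
      states[[length(states) + 1L]] <- list(action = "drop", block = dropped,
                                            p = pv[worst], selected = sel)
      if (steps >= settings$max_steps) break
    }
  }
  structure(list(states = states, selected = sel, flags = flags, n = n,
                 settings = settings, base = base, blocks = blocks, y = y),
            class = "stepwise_path")
}

#' Prune a stepwise path by split-sample cross-validation
#'
#' Revisits every model state along the selection path (including the null,
#' base-only model) and scores it by k-fold cross-validated mean squared
#' prediction error within the training data: lines are shuffled once under
#' the settings seed, striped into folds (line i of the shuffle to fold
#' i mod k), and each state's model is refitted on k-1 folds and scored on
#' the held fold.  The state with minimum CV error wins; ties (within 1e-12
#' relative) go to the model with fewer blocks, then to the earlier state.
#'
#' @param path a `stepwise_path`.
#' @param folds number of folds; defaults to the path settings.
#' @return list with `size` (number of blocks retained), `selected`
#'   (block names), `cv_mse` (per-state CV error), `state_index`.
#' @export
reduce_by_split_cv <- function(path, folds = NULL) {
  stopifnot(inherits(path, "stepwise_path"))
  n <- path$n
  if (is.null(folds)) folds <- path$settings$reduction_folds
  if (folds > n) stop("more folds than observations")
  cand_states <- c(list(character(0)), lapply(path$states, `[[`, "selected"))
  # drop duplicated states (a drop step can recreate an earlier set)
  keys <- vapply(cand_states, function(s) paste(sort(s), collapse = "|"), "")
  keep <- !duplicated(keys)
  cand_states <- cand_states[keep]
  if (length(cand_states) == 1L) {
    return(list(size = 0L, selected = character(0),
                cv_mse = NA_real_, state_index = 1L))
  }
  perm <- with_seed(path$settings$seed, sample.int(n))
  fold_of <- integer(n)
  fold_of[perm] <- (seq_len(n) - 1L) %% folds + 1L
  bidx_cols <- function(sel) {
    if (!length(sel)) return(path$base)
    cbind(path$base, do.call(cbind, path$blocks[sel]))
  }
  cv_mse <- vapply(cand_states, function(sel) {
    X <- bidx_cols(sel)
    sse <- 0
    for (k in seq_len(folds)) {
      tr <- fold_of != k
      fit <- stats::lm.fit(X[tr, , drop = FALSE], path$y[tr])
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      pred <- drop(X[!tr, , drop = FALSE] %*% beta)
      sse <- sse + sum((path$y[!tr] - pred)^2)
    }
    sse / n
  }, 0)
  nblk <- vapply(cand_states, length, 0L)
  best_err <- min(cv_mse)
  tied <- which(cv_mse <= best_err + 1e-12 * max(1, abs(best_err)))
  winner <- tied[order(nblk[tied], tied)][1]
  list(size = nblk[winner], selected = cand_states[[winner]],
       cv_mse = cv_mse, state_index = winner)
}
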