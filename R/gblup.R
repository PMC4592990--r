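#' VanRaden method-1 realized genomic relationship matrix
#'
#' Computes G = ZZ' / (2 * sum_j p_j (1 - p_j)) with Z = M - 2P, where M is
#' the line x marker dosage matrix on the 0..2 scale and the column centering
#' 2p_j uses the non-reference allele frequencies p_j.  Monomorphic markers
#' are excluded from numerator and denominator.  Applied within one family
#' on linkage-marker dosages, G tracks within-family IBD sharing; applied
#' panel-wide on allele calls it is the identity-in-state relationship.
#'
#' @param dosage line x marker matrix.  Values are scaled to 0..2: a matrix
#'   whose maximum is <= 1 (the package's inbred-dosage coding) is doubled.
#' @param allele_freqs `"estimate"` (default: p_j = column mean / 2) or a
#'   numeric vector of frequencies, one per marker column.
#' @param stabilize add `1e-8 * mean(diag)` to the diagonal so downstream
#'   factorizations see a positive semidefinite matrix.
#' @return object of class `gmatrix`: list with `line_ids`, `values`
#'   (symmetric matrix), `provenance`.
#' @examples
#' d <- matrix(c(0, 1), 2, 1, dimnames = list(c("a", "b"), "m1"))
#' vanraden1_g(d)$values  # [[2, -2], [-2, 2]]
#' @export
vanraden1_g <- function(dosage, allele_freqs = "estimate", stabilize = TRUE) {
  M <- as.matrix(dosage)
  if (is.null(rownames(M))) stop("dosage must carry line rownames")
  if (max(M) <= 1 + 1e-12) M <- 2 * M
  if (identical(allele_freqs, "estimate")) {
    p <- colMeans(M) / 2
  } else {
    p <- as.numeric(allele_freqs)
    if (length(p) != ncol(M)) stop("one allele frequency per marker required")
  }
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers monomorphic: G matrix undefined")
  M <- M[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(M, 2L, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  if (stabilize) diag(G) <- diag(G) + 1e-8 * mean(diag(G))
  structure(list(line_ids = rownames(M), values = G,
                 provenance = "vanraden1"),
            class = "gmatrix")
}

#' @export
print.gmatrix <- function(x, ...) {
  cat(sprintf("G matrix (%s): %d lines\n", x$provenance, length(x$line_ids)))
  invisible(x)
}

#' Wrap an externally supplied relationship matrix
#'
#' @param values square symmetric numeric matrix with line ids as dimnames.
#' @param provenance free-text origin label.
#' @return a `gmatrix`.
#' @export
gmatrix <- function(values, provenance = "external") {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("G must carry line-id dimnames")
  if (max(abs(values - t(values))) > 1e-10) stop("G is not symmetric")
  structure(list(line_ids = rownames(values), values = values,
                 provenance = provenance),
            class = "gmatrix")
}

#' Fit a GBLUP model by REML
#'
#' Fits y = X mu + g + e with g ~ (0, G sigma2_g) and e ~ (0, I sigma2_e) on
#' the training lines.  The fixed part is a grand mean (SGBLUP run within
#' one family) or per-family means (the joint-family analog).  Variance
#' components are estimated by REML profiled over the single ratio
#' lambda = sigma2_e / sigma2_g using the spectral decomposition of the
#' projected training block of G, so the whole fit costs one eigen
#' decomposition plus a 1-D optimization in log lambda.
#'
#' @param G a `gmatrix` covering all training (and later test) lines.
#' @param phen phenotype data.frame (`line`, `family`, `value`).
#' @param train_lines training line ids, a subset of the G line ids.
#' @param fixed_effects `"grand_mean"` or `"family_means"`.
#' @param lambda optional fixed ratio sigma2_e/sigma2_g, bypassing REML;
#'   `Inf` gives complete shrinkage to the fixed-effect mean.
#' @return object of class `gblup_fit` with `mu` (fixed-effect
#'   coefficients), `sigma2_g`, `sigma2_e`, `lambda`, `h2`, and solve
#'   artifacts reused by [predict_gblup()].
#' @export
fit_gblup <- function(G, phen, train_lines,
                      fixed_effects = c("grand_mean", "family_means"),
                      lambda = NULL) {
  fixed_effects <- match.arg(fixed_effects)
  stopifnot(inherits(G, "gmatrix"))
  miss <- setdiff(train_lines, G$line_ids)
  if (length(miss)) stop("training lines absent from G: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  y <- .phen_lookup(phen, train_lines)
  if (stats::var(y) == 0) stop("zero phenotypic variance in training data")
  fam <- phen$family[match(train_lines, phen$line)]
  X <- if (fixed_effects == "grand_mean") {
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    f <- sort(unique(fam))
    sapply(f, function(g) as.numeric(fam == g))
  }
  X <- as.matrix(X)
  K <- G$values[train_lines, train_lines, drop = FALSE]
  n <- length(y)
  p <- qr(X)$rank

  if (!is.null(lambda) && is.infinite(lambda)) {
    mu <- stats::lm.fit(X, y)$coefficients
    mu[is.na(mu)] <- 0
    return(structure(list(mu = mu, fixed_effects = fixed_effects,
                          sigma2_g = 0, sigma2_e = stats::var(y),
                          lambda = Inf, h2 = 0,
                          train_lines = train_lines, fam_train = fam,
                          resid = y - drop(X %*% mu), K_train = K),
                     class = "gblup_fit"))
  }

  # REML profile via eigen decomposition of the projected kernel (EMMA-style)
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  es <- eigen(S %*% K %*% S, symmetric = TRUE)
  keep <- seq_len(n - p)
  xi <- es$values[keep]
  xi[xi < 1e-10] <- 1e-10
  eta <- drop(crossprod(es$vectors[, keep, drop = FALSE], y))
  reml_ll <- function(log_lam) {
    lam <- exp(log_lam)
    denom <- xi + lam
    s2 <- sum(eta^2 / denom) / (n - p)
    -0.5 * ((n - p) * log(s2) + sum(log(denom)))
  }
  if (is.null(lambda)) {
    opt <- stats::optimize(reml_ll, interval = c(-18, 18), maximum = TRUE,
                           tol = 1e-8)
    lambda <- exp(opt$maximum)
  }
  sigma2_g <- sum(eta^2 / (xi + lambda)) / (n - p)
  sigma2_e <- lambda * sigma2_g
  # GLS fixed effects at the estimated lambda
  Vi <- solve(K + lambda * diag(n))
  XtVi <- crossprod(X, Vi)
  mu <- solve(XtVi %*% X, XtVi %*% y)
  mu <- stats::setNames(drop(mu), colnames(X))
  resid <- y - drop(X %*% mu)
  # per-line genetic variance is sigma2_g * G_ii; on fully inbred panels
  # the VanRaden diagonal is ~2, so the heritability estimate carries the
  # mean diagonal rather than assuming a standardized G
  gscale <- mean(diag(K))
  structure(list(mu = mu, fixed_effects = fixed_effects,
                 sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 lambda = lambda,
                 h2 = gscale * sigma2_g / (gscale * sigma2_g + sigma2_e),
                 train_lines = train_lines, fam_train = fam,
                 resid = resid, K_train = K,
                 Kinv_resid = drop(solve(K + lambda * diag(n), resid))),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("GBLUP fit (%s): sigma2_g = %.4g, sigma2_e = %.4g, h2 = %.3f\n",
              x$fixed_effects, x$sigma2_g, x$sigma2_e, x$h2))
  invisible(x)
}

#' Predict test lines from a GBLUP fit
#'
#' g_test = G[test, train] (G[train, train] + lambda I)^-1 (y - X mu), and
#' the prediction is the fixed-effect mean plus g_test.  A test line
#' unrelated to every training line therefore predicts at the fixed mean.
#'
#' @param fit a `gblup_fit`.
#' @param G the `gmatrix` used at fit time (must also cover the test lines).
#' @param test_lines line ids disjoint from training.
#' @param phen phenotype table supplying family ids for the output (and for
#'   family-mean fixed effects).
#' @param model_label,test_set_id labels for the output.
#' @return a [prediction_set()].
#' @export
predict_gblup <- function(fit, G, test_lines, phen,
                          model_label = "GBLUP", test_set_id = "test") {
  miss <- setdiff(test_lines, G$line_ids)
  if (length(miss)) stop("test lines absent from G: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  fam <- phen$family[match(test_lines, phen$line)]
  Xt <- if (fit$fixed_effects == "grand_mean") {
    matrix(1, length(test_lines), 1)
  } else {
    f <- names(fit$mu)
    unknown <- setdiff(unique(fam), f)
    if (length(unknown)) stop("no fixed effect for family: ",
                              paste(unknown, collapse = ", "))
    sapply(f, function(g) as.numeric(fam == g))
  }
  fixed <- drop(as.matrix(Xt) %*% fit$mu)
  ghat <- if (is.infinite(fit$lambda)) {
    rep(0, length(test_lines))
  } else {
    Ktt <- G$values[test_lines, fit$train_lines, drop = FALSE]
    drop(Ktt %*% fit$Kinv_resid)
  }
  prediction_set(test_lines, fam, fixed + ghat,
                 model_label = model_label, test_set_id = test_set_id)
}
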