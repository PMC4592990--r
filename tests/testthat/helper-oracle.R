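# Brute-force stepwise oracle: replays the forward/backward protocol but
# recomputes every partial-F p-value from scratch with lm()/anova() instead
# of the package's incremental QR arithmetic.  Used to check that every
# entry/removal decision of stepwise_select() matches an independent
# computation.
oracle_stepwise <- function(y, blocks, base = NULL, alpha, max_steps = 200) {
  n <- length(y)
  if (is.null(base)) base <- matrix(1, n, 1)
  blocks <- lapply(blocks, as.matrix)
  partial_p <- function(sel, extra) {
    X0 <- if (length(sel)) cbind(base, do.call(cbind, blocks[sel])) else base
    X1 <- cbind(X0, blocks[[extra]])
    f0 <- stats::lm(y ~ X0 - 1)
    f1 <- stats::lm(y ~ X1 - 1)
    a <- stats::anova(f0, f1)
    q <- a$Df[2]
    if (is.na(q) || q <= 0) return(NA_real_)
    if (a$Res.Df[2] <= 0) return(NA_real_)
    rss1 <- a$RSS[2]
    if (rss1 <= .Machine$double.eps * max(a$RSS[1], 1)) return(0)
    a$`Pr(>F)`[2]
  }
  drop_p <- function(sel, b) {
    X1 <- cbind(base, do.call(cbind, blocks[sel]))
    X0 <- if (length(setdiff(sel, b)))
      cbind(base, do.call(cbind, blocks[setdiff(sel, b)])) else base
    f0 <- stats::lm(y ~ X0 - 1)
    f1 <- stats::lm(y ~ X1 - 1)
    a <- stats::anova(f0, f1)
    q <- a$Df[2]
    if (is.na(q) || q <= 0) return(1)
    if (a$RSS[2] <= .Machine$double.eps * max(a$RSS[1], 1)) return(0)
    a$`Pr(>F)`[2]
  }
  sel <- character(0)
  states <- list()
  steps <- 0L
  if (stats::var(y) == 0 || !length(blocks)) {
    return(list(states = states, selected = sel))
  }
  repeat {
    if (steps >= max_steps) break
    cands <- setdiff(names(blocks), sel)
    if (!length(cands)) break
    pv <- vapply(cands, function(b) partial_p(sel, b), 0)
    if (all(is.na(pv))) break
    best <- which.min(pv)
    if (!(pv[best] < alpha)) break
    sel <- c(sel, cands[best])
    steps <- steps + 1L
    states[[length(states) + 1L]] <- list(action = "add", block = cands[best])
    repeat {
      if (length(sel) < 2L) break
      dp <- vapply(sel, function(b) drop_p(sel, b), 0)
      worst <- which.max(dp)
      if (dp[worst] < alpha) break
      dropped <- sel[worst]
      sel <- setdiff(sel, dropped)
      steps <- steps + 1L
      states[[length(states) + 1L]] <- list(action = "drop", block = dropped)
      if (steps >= max_steps) break
    }
  }
  list(states = states, selected = sel)
}

decisions_of <- function(path_or_oracle) {
  vapply(path_or_oracle$states,
         function(s) paste(s$action, s$block), "")
}
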