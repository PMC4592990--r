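#' Construct a linkage map
#'
#' A linkage map is an ordered table of markers with a linkage-group
#' (chromosome) identifier and a genetic position in centimorgans.  It is the
#' substrate that map thinning operates on: every QTL base learner in a
#' TAGGING ensemble works on one thinned sub-map of a parent map.
#'
#' @param marker character vector of unique marker ids.
#' @param chrom linkage-group identifiers (coerced to character).
#' @param cM nonnegative, finite genetic positions in centimorgans.
#' @param sort if `TRUE` (default) rows are sorted by `(chrom, cM)`; if
#'   `FALSE` the input order must already be sorted.
#' @return A `data.frame` of class `linkage_map` with columns `marker`,
#'   `chrom`, `cM`, carrying attributes `is_uniform` (logical) and
#'   `spacing_cM` (the common adjacent spacing when uniform, otherwise `NA`).
#' @examples
#' m <- linkage_map(paste0("m", 1:10), rep(1, 10), seq(0, 1.8, by = 0.2))
#' attr(m, "is_uniform")
#' @export
linkage_map <- function(marker, chrom, cM, sort = TRUE) {
  marker <- as.character(marker)
  chrom <- as.character(chrom)
  cM <- as.numeric(cM)
  if (length(marker) == 0L) stop("empty map")
  if (anyDuplicated(marker)) {
    stop("duplicate marker ids: ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "))
  }
  if (any(!is.finite(cM)) || any(cM < 0)) {
    stop("positions must be finite and >= 0 cM")
  }
  df <- data.frame(marker = marker, chrom = chrom, cM = cM,
                   stringsAsFactors = FALSE)
  if (sort) df <- df[order(df$chrom, df$cM), , drop = FALSE]
  rownames(df) <- NULL
  for (g in unique(df$chrom)) {
    pos <- df$cM[df$chrom == g]
    if (is.unsorted(pos, strictly = TRUE)) {
      stop("positions not strictly increasing within group ", g)
    }
  }
  sp <- .map_spacings(df)
  uniform <- length(sp) > 0L && max(sp) - min(sp) <= .map_tol
  structure(df,
            class = c("linkage_map", "data.frame"),
            is_uniform = uniform,
            spacing_cM = if (uniform) sp[1] else NA_real_)
}

# absolute tolerance for declaring adjacent spacings equal
.map_tol <- 1e-9

.map_spacings <- function(df) {
  unlist(lapply(split(df$cM, df$chrom), diff), use.names = FALSE)
}

#' @export
print.linkage_map <- function(x, ...) {
  cat(sprintf("linkage map: %d markers on %d group(s)%s\n",
              nrow(x), length(unique(x$chrom)),
              if (isTRUE(attr(x, "is_uniform")))
                sprintf(", uniform %.4g cM", attr(x, "spacing_cM")) else ""))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Diagnose structural problems in a linkage map
#'
#' Reports (but does not repair) duplicate marker ids, non-monotone positions
#' within a linkage group, and violations of a claimed uniform spacing.
#'
#' @param map a `linkage_map` or a bare data.frame with columns
#'   `marker`, `chrom`, `cM`.
#' @return Character vector of diagnostics; empty for a well-formed map.
#' @export
validate_map <- function(map) {
  out <- character(0)
  if (anyDuplicated(map$marker)) {
    out <- c(out, paste0("duplicate id: ",
                         paste(unique(map$marker[duplicated(map$marker)]),
                               collapse = ", ")))
  }
  for (g in unique(map$chrom)) {
    pos <- map$cM[map$chrom == g]
    if (is.unsorted(pos, strictly = TRUE)) {
      out <- c(out, paste0("non-monotone positions in group ", g))
    }
  }
  if (isTRUE(attr(map, "is_uniform"))) {
    sp <- .map_spacings(map)
    if (length(sp) && max(sp) - min(sp) > .map_tol) {
      out <- c(out, sprintf("spacing violation: claimed uniform but spacings range %.6g-%.6g cM",
                            min(sp), max(sp)))
    }
  }
  out
}

#' Thin a linkage map into disjoint stride sub-maps
#'
#' Partitions a map into `s` disjoint sub-maps by stratified (stride)
#' sampling of markers: sub-map *k* takes markers at within-stratum indices
#' *k, k+s, k+2s, ...*.  On a uniform map with spacing *d* this yields `s`
#' uniform sub-maps with spacing *s·d*.  Each sub-map then serves as the
#' hypothesis space of one QTL base learner.
#'
#' @param map a `linkage_map`.
#' @param s positive integer thinning factor (number of sub-maps); must not
#'   exceed the number of markers on the smallest linkage group.
#' @param phase_policy `"per_group_restart"` (default) restarts the stride
#'   phase at the first marker of every linkage group — genetic distance is
#'   only meaningful within a group; `"continuous"` carries the marker index
#'   across group boundaries.
#' @return An object of class `thinned_map_set`: a list with elements
#'   `parent`, `s`, `phase_policy` and `submaps` (a list of `s`
#'   `linkage_map`s forming a partition of the parent's markers).
#' @examples
#' m <- linkage_map(paste0("m", 1:10), rep(1, 10), seq(0, 1.8, by = 0.2))
#' ts <- thin_map(m, 2)
#' sapply(ts$submaps, nrow)
#' @export
thin_map <- function(map, s,
                     phase_policy = c("per_group_restart", "continuous")) {
  phase_policy <- match.arg(phase_policy)
  s <- as.integer(s)
  if (length(s) != 1L || is.na(s) || s < 1L) stop("s must be a positive integer")
  grp_n <- table(map$chrom)
  if (s > min(grp_n)) {
    small <- names(grp_n)[which.min(grp_n)]
    stop(sprintf("s = %d exceeds the %d markers on the smallest linkage group (%s)",
                 s, min(grp_n), small))
  }
  idx <- seq_len(nrow(map))
  if (phase_policy == "per_group_restart") {
    within <- stats::ave(idx, map$chrom, FUN = seq_along)
  } else {
    within <- idx
  }
  stratum <- ((within - 1L) %% s) + 1L
  submaps <- lapply(seq_len(s), function(k) {
    sub <- map[stratum == k, , drop = FALSE]
    linkage_map(sub$marker, sub$chrom, sub$cM, sort = FALSE)
  })
  structure(list(parent = map, s = s, phase_policy = phase_policy,
                 submaps = submaps),
            class = "thinned_map_set")
}

#' Thin a non-uniform map by target spacing
#'
#' Generalizes stride thinning to unevenly spaced maps: each linkage group is
#' binned into consecutive windows of width `target_spacing_cM` (anchored at
#' the group's first marker) and sub-map *k* takes the *k*-th marker of every
#' window.  Windows holding fewer markers contribute to fewer sub-maps, and
#' gaps wider than the target leave empty windows; the partition property
#' always holds.  On a uniform map with spacing *d* and target *s·d* the
#' result coincides with `thin_map(map, s)`.
#'
#' @param map a `linkage_map`.
#' @param target_spacing_cM positive window width; must be at least the
#'   smallest adjacent within-group spacing already present (below that,
#'   every window holds at most one marker and no thinning can occur).
#'   Gaps wider than the target simply leave empty windows.
#' @return A `thinned_map_set`; the number of sub-maps equals the maximum
#'   number of markers found in any window.
#' @export
thin_map_by_distance <- function(map, target_spacing_cM) {
  if (!is.numeric(target_spacing_cM) || target_spacing_cM <= 0) {
    stop("target_spacing_cM must be positive")
  }
  sp <- .map_spacings(map)
  if (length(sp) && target_spacing_cM < min(sp) - .map_tol) {
    stop(sprintf("target spacing %.4g cM is smaller than the existing minimum adjacent spacing %.4g cM",
                 target_spacing_cM, min(sp)))
  }
  stratum <- integer(nrow(map))
  for (g in unique(map$chrom)) {
    sel <- which(map$chrom == g)
    pos <- map$cM[sel]
    win <- floor((pos - pos[1]) / target_spacing_cM + .map_tol)
    stratum[sel] <- stats::ave(seq_along(sel), win, FUN = seq_along)
  }
  s_eff <- max(stratum)
  submaps <- lapply(seq_len(s_eff), function(k) {
    sub <- map[stratum == k, , drop = FALSE]
    linkage_map(sub$marker, sub$chrom, sub$cM, sort = FALSE)
  })
  structure(list(parent = map, s = s_eff,
                 phase_policy = "per_group_restart", submaps = submaps),
            class = "thinned_map_set")
}

#' @export
print.thinned_map_set <- function(x, ...) {
  cat(sprintf("thinned map set: s = %d (%s), sub-map sizes %s\n",
              x$s, x$phase_policy,
              paste(vapply(x$submaps, nrow, 0L), collapse = "/")))
  invisible(x)
}
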