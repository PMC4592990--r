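#' Configuration for the synthetic multi-family RIL panel
#'
#' Describes a NAM-like design: `n_families` biparental RIL families sharing
#' one reference parent, genotyped on a uniform-spacing linkage map, with a
#' fixed additive QTL architecture and a target line-mean heritability.
#' Defaults describe a 5-family, 1000-line panel on a 5 x 200-marker map at
#' the 0.2-cM pseudomarker density typical of imputed NAM maps (so adjacent
#' markers are strongly collinear, the regime map thinning addresses),
#' carrying eight additive QTL (four large, four small) and heritability
#' 0.7 — large enough for ensemble behaviour to show, small enough to run
#' on one CPU in minutes.
#'
#' @param n_families number of biparental RIL families (the panel's P).
#' @param lines_per_family RILs per family.
#' @param n_groups number of linkage groups.
#' @param markers_per_group markers per group.
#' @param spacing_cM uniform intermarker distance in centimorgans.
#' @param qtl data.frame with columns `chrom`, `cM`, and one numeric effect
#'   column per family (`eff1`..`effP`): additive substitution effects of the
#'   non-reference allele, relative to the reference parent.  `NULL` uses
#'   [default_qtl_architecture()].
#' @param heritability target line-mean heritability in (0, 1], enforced at
#'   the panel level.
#' @param founder_polymorphism_rate probability that a marker's founder
#'   allele differs from the reference parent in a given family, i.e. that
#'   the marker segregates in that family.
#' @param seed integer seed; identical configs give bit-identical panels.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_families = 5, lines_per_family = 200,
                       n_groups = 5, markers_per_group = 200,
                       spacing_cM = 0.2, qtl = NULL,
                       heritability = 0.7,
                       founder_polymorphism_rate = 0.9,
                       seed = 1L) {
  if (heritability <= 0 || heritability > 1) stop("heritability must be in (0, 1]")
  if (founder_polymorphism_rate <= 0 || founder_polymorphism_rate > 1) {
    stop("founder_polymorphism_rate must be in (0, 1]")
  }
  if (is.null(qtl)) qtl <- default_qtl_architecture(n_families)
  extent <- (markers_per_group - 1) * spacing_cM
  if (any(qtl$cM < 0 | qtl$cM > extent)) {
    stop("QTL position outside the map extent [0, ", extent, "] cM")
  }
  eff_cols <- paste0("eff", seq_len(n_families))
  if (!all(eff_cols %in% names(qtl))) {
    stop("qtl must carry effect columns ", paste(eff_cols, collapse = ", "))
  }
  structure(list(n_families = as.integer(n_families),
                 lines_per_family = as.integer(lines_per_family),
                 n_groups = as.integer(n_groups),
                 markers_per_group = as.integer(markers_per_group),
                 spacing_cM = spacing_cM, qtl = qtl,
                 heritability = heritability,
                 founder_polymorphism_rate = founder_polymorphism_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default eight-QTL architecture
#'
#' Eight additive QTL concentrated on linkage groups 1-4 (groups kept free of
#' QTL provide null regions for detection-specificity checks): four large
#' QTL (base effect 1.0) and four small (base effect 0.4).  Family-specific
#' effects scale the base effect by a deterministic factor in \[0.7, 1.3\] so
#' that allele effects differ between families, as in a multi-founder panel.
#' Positions sit inside the default 39.8-cM groups of the 0.2-cM map.
#'
#' @param n_families number of families (effect columns).
#' @return data.frame with columns `chrom`, `cM`, `eff1`..`effP`.
#' @export
default_qtl_architecture <- function(n_families = 5) {
  base <- data.frame(
    chrom = as.character(c(1, 1, 2, 2, 3, 3, 4, 4)),
    cM = c(6, 14, 10, 30, 8, 12, 6, 14),
    size = c(1.0, 0.4, 1.0, 0.4, 1.0, 0.4, 1.0, 0.4))
  for (f in seq_len(n_families)) {
    # deterministic family-by-locus modulation, no RNG involved
    fac <- 0.7 + 0.6 * (((seq_len(nrow(base)) * 3 + f * 5) %% 7) / 6)
    base[[paste0("eff", f)]] <- base$size * fac
  }
  base$size <- NULL
  base
}

#' Haldane recombination fraction at RIL (selfing) scale
#'
#' Maps genetic distance to the probability that two adjacent loci carry
#' different parental alleles in a fully inbred RIL: the meiotic Haldane
#' fraction r = (1 - exp(-2d/100))/2 is inflated to R = 2r/(1+2r) to account
#' for the recombination accumulated over repeated selfing.
#'
#' @param d_cM vector of genetic distances in centimorgans.
#' @return vector of RIL-scale recombination fractions in [0, 0.5].
#' @export
ril_recomb_fraction <- function(d_cM) {
  r <- 0.5 * (1 - exp(-2 * d_cM / 100))
  2 * r / (1 + 2 * r)
}

#' Simulate a NAM-like multi-family RIL panel
#'
#' Per family, founder alleles are drawn polymorphic against the reference
#' parent with probability `founder_polymorphism_rate` independently per
#' marker.  RIL genomes are generated by a Markov walk along each linkage
#' group with transition probability [ril_recomb_fraction()] of the adjacent
#' map distance; lines are fully inbred, so dosages are in \{0, 1\}.  Genetic
#' values are the inner product of the *latent* (unmasked) dosage at the
#' marker nearest each QTL with the family-specific QTL effects; a family's
#' observed marker column is zeroed wherever its founder carries the
#' reference allele, so a QTL can be invisible at its own position in some
#' families yet tagged by neighbours in others.  Environmental noise is
#' scaled from the realized panel-level genetic variance so the line-mean
#' heritability matches the target.
#'
#' @param config a [sim_config()].
#' @return list with elements `panel` (a `genotype_panel`), `phen`
#'   (data.frame `line`, `family`, `value`) and `truth` (QTL marker ids,
#'   positions, per-family effects, the noise variance `sigma2_e`, and the
#'   realized heritability).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    P <- config$n_families
    nf <- config$lines_per_family
    m_per <- config$markers_per_group
    G <- config$n_groups
    M <- m_per * G
    map <- linkage_map(
      marker = paste0("m", seq_len(M)),
      chrom = as.character(rep(seq_len(G), each = m_per)),
      cM = rep(seq(0, by = config$spacing_cM, length.out = m_per), G))
    Rfrac <- ril_recomb_fraction(config$spacing_cM)

    fam_ids <- paste0("F", seq_len(P))
    line_ids <- unlist(lapply(fam_ids, function(f) paste0(f, "_", seq_len(nf))))
    family <- rep(fam_ids, each = nf)

    latent <- matrix(0L, nrow = P * nf, ncol = M)
    dosage <- matrix(0, nrow = P * nf, ncol = M,
                     dimnames = list(line_ids, map$marker))
    for (fi in seq_len(P)) {
      rows <- (fi - 1L) * nf + seq_len(nf)
      poly <- stats::runif(M) < config$founder_polymorphism_rate
      lat <- matrix(0L, nrow = nf, ncol = M)
      for (g in seq_len(G)) {
        cols <- (g - 1L) * m_per + seq_len(m_per)
        x <- as.integer(stats::runif(nf) < 0.5)
        lat[, cols[1]] <- x
        for (j in 2:m_per) {
          flip <- stats::runif(nf) < Rfrac
          x <- ifelse(flip, 1L - x, x)
          lat[, cols[j]] <- x
        }
      }
      latent[rows, ] <- lat
      dosage[rows, ] <- sweep(lat, 2L, as.numeric(poly), `*`)
    }

    # snap each QTL to the nearest marker of its group; genetic value uses
    # the latent dosage there so the effect table alone controls segregation
    qtl <- config$qtl
    qtl_marker <- character(nrow(qtl))
    gvalue <- numeric(P * nf)
    eff_mat <- as.matrix(qtl[, paste0("eff", seq_len(P)), drop = FALSE])
    for (q in seq_len(nrow(qtl))) {
      on_g <- which(map$chrom == qtl$chrom[q])
      if (!length(on_g)) stop("QTL on unknown linkage group ", qtl$chrom[q])
      j <- on_g[which.min(abs(map$cM[on_g] - qtl$cM[q]))]
      qtl_marker[q] <- map$marker[j]
      per_line_eff <- eff_mat[q, match(family, fam_ids)]
      gvalue <- gvalue + latent[, j] * per_line_eff
    }

    var_g <- stats::var(gvalue)
    h2 <- config$heritability
    if (var_g == 0 && h2 < 1) {
      stop("zero genetic variance: target heritability < 1 is infeasible")
    }
    sigma2_e <- if (h2 == 1) 0 else var_g * (1 - h2) / h2
    y <- gvalue + if (sigma2_e > 0)
      stats::rnorm(P * nf, 0, sqrt(sigma2_e)) else 0

    panel <- genotype_panel(dosage, family, map)
    phen <- data.frame(line = line_ids, family = family, value = y,
                       stringsAsFactors = FALSE)
    truth <- list(qtl = data.frame(marker = qtl_marker, chrom = qtl$chrom,
                                   cM = map$cM[match(qtl_marker, map$marker)],
                                   qtl[, paste0("eff", seq_len(P)), drop = FALSE],
                                   stringsAsFactors = FALSE),
                  sigma2_e = sigma2_e,
                  genetic_values = stats::setNames(gvalue, line_ids),
                  var_genetic = var_g,
                  realized_h2 = if (var_g + sigma2_e > 0)
                    var_g / (var_g + sigma2_e) else 1,
                  map_function = "haldane")
    list(panel = panel, phen = phen, truth = truth)
  })
}

#' Construct a genotype panel
#'
#' The shared genotype container of the QTL and GBLUP paths: a line x marker
#' matrix of expected dosages of the non-reference-parent allele (0 =
#' reference-parent homozygote) plus the family assignment and linkage map.
#'
#' @param dosage numeric matrix, rows = lines (rownames = line ids),
#'   columns = markers (colnames = marker ids), values in [0, 1].
#' @param family character vector of family ids, one per line.
#' @param map the `linkage_map` the columns refer to.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosage, family, map) {
  if (is.null(rownames(dosage)) || is.null(colnames(dosage))) {
    stop("dosage must carry line rownames and marker colnames")
  }
  if (length(family) != nrow(dosage)) stop("one family id per line required")
  bad <- which(dosage < 0 | dosage > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("dosage outside [0, 1] at line %s, marker %s",
                 rownames(dosage)[bad[1, 1]], colnames(dosage)[bad[1, 2]]))
  }
  missing_mk <- setdiff(colnames(dosage), map$marker)
  if (length(missing_mk)) {
    stop("markers absent from the map: ",
         paste(utils::head(missing_mk, 5), collapse = ", "))
  }
  structure(list(dosage = dosage,
                 line_ids = rownames(dosage),
                 family = stats::setNames(as.character(family),
                                          rownames(dosage)),
                 map = map),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype panel: %d lines in %d families x %d markers\n",
              length(x$line_ids), length(unique(x$family)),
              ncol(x$dosage)))
  invisible(x)
}

# Run code under a temporary RNG state so simulation and fitting are
# reproducible without clobbering the caller's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
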