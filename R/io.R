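#' @title Delimited-text readers and writers
#' @description All on-disk formats are plain text.  Map files are
#'   tab-separated with header `marker`, `chrom`, `cM`; genotype files are
#'   line x marker TSVs with leading `line` and `family` columns; phenotype
#'   files carry `line`, `family`, `value`; G-matrix files are square TSVs
#'   with line ids as header and first column.  Readers validate structure
#'   and cross-consistency, writers emit the same dialect they read.
#' @name tagging_io
NULL

#' @rdname tagging_io
#' @param path file path.
#' @return `read_map` returns a `linkage_map`.
#' @export
read_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "cM")
  if (!all(need %in% names(df))) {
    stop("map file must have header marker\tchrom\tcM")
  }
  linkage_map(df$marker, df$chrom, df$cM)
}

#' @rdname tagging_io
#' @param map a `linkage_map`.
#' @export
write_map <- function(map, path) {
  utils::write.table(as.data.frame(map)[, c("marker", "chrom", "cM")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tagging_io
#' @param map_path optional map file used to validate marker coverage.
#' @return `read_genotypes` returns a `genotype_panel`.
#' @export
read_genotypes <- function(path, map_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("line", "family") %in% names(df)[1:2])) {
    stop("genotype file must start with columns line, family")
  }
  mk <- setdiff(names(df), c("line", "family"))
  dos <- as.matrix(df[, mk, drop = FALSE])
  rownames(dos) <- df$line
  bad <- which(dos < 0 | dos > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("dosage outside [0, 1] at line %s, marker %s",
                 df$line[bad[1, 1]], mk[bad[1, 2]]))
  }
  map <- if (!is.null(map_path)) {
    read_map(map_path)
  } else {
    linkage_map(mk, rep("1", length(mk)), seq_along(mk) - 1, sort = FALSE)
  }
  extra <- setdiff(mk, map$marker)
  if (length(extra)) stop("genotyped markers absent from the map: ",
                          paste(utils::head(extra, 5), collapse = ", "))
  genotype_panel(dos[, map$marker[map$marker %in% mk], drop = FALSE],
                 df$family, map)
}

#' @rdname tagging_io
#' @param panel a `genotype_panel`.
#' @export
write_genotypes <- function(panel, path) {
  df <- data.frame(line = panel$line_ids,
                   family = unname(panel$family[panel$line_ids]),
                   panel$dosage, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tagging_io
#' @return `read_phenotypes` returns a data.frame `line`, `family`, `value`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("line", "family", "value")
  if (!all(need %in% names(df))) {
    stop("phenotype file must have columns line, family, value")
  }
  if (any(!is.finite(df$value))) stop("non-finite phenotype values")
  df[, need]
}

#' @rdname tagging_io
#' @param phen phenotype data.frame.
#' @export
write_phenotypes <- function(phen, path) {
  utils::write.table(phen[, c("line", "family", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tagging_io
#' @return `read_gmatrix` returns a `gmatrix`.
#' @export
read_gmatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1,
                          stringsAsFactors = FALSE)
  gmatrix(as.matrix(df), provenance = "external")
}

#' @rdname tagging_io
#' @param G a `gmatrix`.
#' @export
write_gmatrix <- function(G, path) {
  df <- data.frame(line = G$line_ids, G$values, check.names = FALSE)
  colnames(df) <- c("line", G$line_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tagging_io
#' @param preds a `prediction_set`.
#' @export
write_predictions <- function(preds, path) {
  utils::write.table(as.data.frame(preds), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a thinned map set to disk
#'
#' One map file per sub-map plus a JSON manifest recording the parent map
#' digest, the thinning factor, the phase policy, and the sub-map files.
#'
#' @param thinned a `thinned_map_set`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix for the sub-map files.
#' @return the manifest path, invisibly.
#' @export
write_thinned_maps <- function(thinned, dir, prefix = "submap") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(thinned$s)
  for (k in seq_len(thinned$s)) {
    files[k] <- file.path(dir, sprintf("%s_%02d.tsv", prefix, k))
    write_map(thinned$submaps[[k]], files[k])
  }
  parent_hash <- sum(utf8ToInt(paste(thinned$parent$marker, collapse = "")))
  manifest <- list(parent_hash = parent_hash, s = thinned$s,
                   phase_policy = thinned$phase_policy,
                   submap_files = basename(files))
  mpath <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}

#' Serialize a QTL fit to JSON
#'
#' @param fit a `qtl_fit`.
#' @param path output path.
#' @export
write_qtl_fit <- function(fit, path) {
  obj <- list(kind = fit$kind, family = fit$family,
              alpha = fit$settings$alpha,
              intercepts = as.list(fit$intercepts),
              loci = lapply(names(fit$effects), function(m)
                list(marker = m, effects = as.list(fit$effects[[m]]))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
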