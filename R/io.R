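# Delimited-text readers/writers for genotypes, phenotypes, chains and
# manifests.  Formats: genotype file = first column individual IDs, header
# row marker IDs, cells 0/1/2 or real dosages ("NA" allowed); phenotype
# file = two columns (ID, trait value).  Delimiter (tab or comma) is
# auto-detected on read.

.detect_sep <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a genotype file
#'
#' @param path delimited text file: header = marker IDs, first column =
#'   individual IDs, cells numeric (or `NA`).
#' @return raw numeric matrix with dimnames (not centred).
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  dt <- data.table::fread(path, sep = .detect_sep(path), header = TRUE,
                          data.table = FALSE)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric genotype codes in ", path)
  rownames(m) <- ids
  m
}

#' Write a genotype matrix (raw codes) to delimited text
#' @param raw numeric matrix with dimnames.
#' @param path output path (tab-separated).
#' @export
write_genotypes <- function(raw, path) {
  dt <- data.table::data.table(id = rownames(raw))
  for (j in seq_len(ncol(raw))) dt[[colnames(raw)[j]]] <- raw[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a phenotype file (ID, value)
#' @param path two-column delimited text file.
#' @return named numeric vector.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  dt <- data.table::fread(path, sep = .detect_sep(path), header = TRUE,
                          data.table = FALSE)
  if (ncol(dt) < 2) stop("phenotype file must have two columns (id, value)")
  phenotypes(as.numeric(dt[[2]]), as.character(dt[[1]]))
}

#' Write phenotypes to delimited text
#' @param y named numeric vector.
#' @param path output path.
#' @export
write_phenotypes <- function(y, path) {
  data.table::fwrite(data.table::data.table(id = names(y), value = as.numeric(y)),
                     path, sep = "\t")
  invisible(path)
}

#' Align phenotypes to a genotype matrix by individual ID
#'
#' Join is order-insensitive; individuals missing on either side raise an
#' error.
#'
#' @param raw raw genotype matrix with row names.
#' @param y named phenotype vector.
#' @return phenotype vector reordered to match `rownames(raw)`.
#' @export
align_phenotypes <- function(raw, y) {
  ids <- rownames(raw)
  if (is.null(ids) || is.null(names(y)))
    stop("both genotypes and phenotypes need individual IDs for joining")
  miss <- setdiff(ids, names(y))
  if (length(miss))
    stop("no phenotype for individual(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  y[ids]
}

#' Write stored chain draws to delimited text
#'
#' Columns: `iteration`, `mu`, `sigma2_e`, `alpha_<marker>` for every
#' marker.
#'
#' @param draws a [run_chain()] result.
#' @param path output path (tab-separated).
#' @export
write_chain <- function(draws, path) {
  dt <- data.table::data.table(iteration = draws$iterations,
                               mu = draws$mu, sigma2_e = draws$sigma2_e)
  a <- data.table::as.data.table(draws$alpha)
  data.table::setnames(a, paste0("alpha_", draws$marker_ids))
  data.table::fwrite(cbind(dt, a), path, sep = "\t")
  invisible(path)
}

#' Read a chain file written by [write_chain()]
#' @param path chain file.
#' @return list with `iterations`, `mu`, `sigma2_e`, `alpha` matrix,
#'   `marker_ids`, `delta_freq` (nonzero frequency of each stored alpha).
#' @export
read_chain <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  acol <- grep("^alpha_", names(dt))
  alpha <- as.matrix(dt[, acol, drop = FALSE])
  ids <- sub("^alpha_", "", names(dt)[acol])
  colnames(alpha) <- ids
  list(iterations = dt$iteration, mu = dt$mu, sigma2_e = dt$sigma2_e,
       alpha = alpha, marker_ids = ids,
       delta_freq = colMeans(alpha != 0))
}

#' Write a run manifest (JSON)
#'
#' Records everything needed to reproduce a run exactly: the resolved
#' configuration, seed, input-file checksums, package version and wall
#' time.
#'
#' @param manifest named list.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a manifest written by [write_manifest()]
#' @param path manifest file.
#' @return named list.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
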