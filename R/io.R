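#' Read a delimited count table
#'
#' Parses a TSV/CSV count table with a header row of taxon (or sample)
#' labels and a first column of row labels, validates it, and returns a
#' preprocessed [preprocess()] object. The delimiter is sniffed from the
#' file extension and first line unless given.
#'
#' @param path Path to the table.
#' @param taxa_are_rows Logical; `TRUE` if rows are taxa.
#' @param covariate_path Optional two-column file (sample_id, value) with a
#'   header, matched to the sample labels.
#' @param sep Field separator; `NULL` to sniff (`","` for `.csv`, else tab).
#' @return A `zippca_counts` object.
#' @export
read_count_table <- function(path, taxa_are_rows = FALSE,
                             covariate_path = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    l1 <- readLines(path, n = 1)
    if (!grepl(sep, l1, fixed = TRUE) && grepl(",", l1, fixed = TRUE)) {
      sep <- ","
    }
  }
  nf <- utils::count.fields(path, sep = sep, quote = "\"")
  if (length(unique(nf)) > 1) {
    stop(sprintf("ragged table: line %d has %d fields, expected %d",
                 which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1]))
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  labs <- as.character(tab[[1]])
  if (anyDuplicated(labs)) {
    stop("duplicate row labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  if (anyDuplicated(colnames(tab)[-1])) {
    stop("duplicate column labels: ",
         paste(unique(colnames(tab)[-1][duplicated(colnames(tab)[-1])]),
               collapse = ", "))
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(m), nrow(m)))) & !is.na(m), arr.ind = TRUE)
    cell <- if (nrow(bad)) sprintf(" (e.g. row %s, column %s: %s)",
                                   labs[bad[1, 1]], colnames(m)[bad[1, 2]],
                                   m[bad[1, 1], bad[1, 2]]) else ""
    stop("non-numeric entries in count table", cell)
  }
  rownames(m) <- labs
  covariate <- NULL
  if (!is.null(covariate_path)) {
    ids <- if (taxa_are_rows) colnames(m) else rownames(m)
    covariate <- read_covariate(covariate_path, ids)
  }
  preprocess(m, taxa_are_rows = taxa_are_rows, covariate = covariate)
}

read_covariate <- function(path, sample_ids) {
  if (!file.exists(path)) stop("covariate file not found: ", path)
  cov <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  if (ncol(cov) < 2) stop("covariate file needs columns: sample_id, value")
  idx <- match(sample_ids, as.character(cov[[1]]))
  if (any(is.na(idx))) {
    stop("covariate file is missing samples: ",
         paste(sample_ids[is.na(idx)], collapse = ", "))
  }
  as.numeric(cov[[2]][idx])
}

#' Read a MatrixMarket triplet count table
#'
#' @param path Path to the `.mtx` triplet file (rows = samples unless
#'   `taxa_are_rows`).
#' @param sample_path,taxon_path Plain-text label files, one label per line.
#' @param taxa_are_rows Logical; `TRUE` if the matrix rows are taxa.
#' @return A `zippca_counts` object.
#' @export
read_count_mtx <- function(path, sample_path, taxon_path,
                           taxa_are_rows = FALSE) {
  m <- tryCatch(as.matrix(Matrix::readMM(path)),
                error = function(e) stop("failed to parse MatrixMarket file ",
                                         path, ": ", conditionMessage(e)))
  rl <- readLines(if (taxa_are_rows) taxon_path else sample_path)
  cl <- readLines(if (taxa_are_rows) sample_path else taxon_path)
  if (length(rl) != nrow(m) || length(cl) != ncol(m)) {
    stop(sprintf("label files (%d, %d) do not match matrix dimensions %d x %d",
                 length(rl), length(cl), nrow(m), ncol(m)))
  }
  dimnames(m) <- list(rl, cl)
  preprocess(m, taxa_are_rows = taxa_are_rows)
}

write_tsv_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m),
                   format(m, digits = 17, scientific = TRUE, trim = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  m
}

#' Write fit artifacts to a directory
#'
#' Serializes a `zippca_fit` as plain-text files: TSV matrices with labels
#' for the loadings `B`, scores `m`, posterior variances `S` and
#' zero-inflation posteriors `pi`; a JSON file with all scalar/vector
#' parameters, the ELBO trace and the configuration; and a manifest listing
#' every file with shapes, the seed and the package version. Files are
#' staged in a temporary directory and moved into place at the end, so a
#' failed write never leaves a partial output directory.
#'
#' @param fit A `zippca_fit`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_artifacts <- function(fit, dir) {
  stopifnot(inherits(fit, "zippca_fit"))
  stage <- tempfile("zippca_stage_")
  dir.create(stage, recursive = TRUE)
  mats <- list(B = fit$params$B, m = fit$varparams$m, S = fit$varparams$S,
               pi = fit$varparams$pi)
  for (nm in names(mats)) {
    write_tsv_matrix(mats[[nm]], file.path(stage, paste0(nm, ".tsv")))
  }
  fitjson <- list(
    params = fit$params[c("c", "tau", "alpha0", "beta0", "phi", "gamma")],
    elbo_trace = fit$elbo_trace, converged = fit$converged,
    n_iter = fit$n_iter, config = unclass(fit$config),
    sample_ids = fit$data$sample_ids, taxon_ids = fit$data$taxon_ids,
    covariate = fit$data$covariate, diagnostics = fit$diagnostics)
  jsonlite::write_json(fitjson, file.path(stage, "fit.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(paste0(names(mats), ".tsv"), "fit.json")
  manifest <- list(
    files = files,
    shapes = lapply(mats, dim),
    seed = fit$config$seed,
    package_version = as.character(utils::packageVersion("zippca")))
  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (f in c(files, "manifest.json")) {
    file.copy(file.path(stage, f), file.path(dir, f), overwrite = TRUE)
  }
  unlink(stage, recursive = TRUE)
  invisible(manifest)
}

#' Reload fit artifacts written by [write_artifacts()]
#'
#' @param dir Directory containing the artifacts.
#' @return A `zippca_fit` (without the original count matrix; the
#'   denoising and composition operations are fully reconstructible).
#' @export
read_artifacts <- function(dir) {
  fj <- jsonlite::read_json(file.path(dir, "fit.json"),
                            simplifyVector = TRUE)
  params <- fj$params
  params$B <- read_tsv_matrix(file.path(dir, "B.tsv"))
  varparams <- list(m = read_tsv_matrix(file.path(dir, "m.tsv")),
                    S = read_tsv_matrix(file.path(dir, "S.tsv")),
                    pi = read_tsv_matrix(file.path(dir, "pi.tsv")))
  config <- fj$config
  class(config) <- "zippca_config"
  structure(list(params = params, varparams = varparams,
                 elbo_trace = fj$elbo_trace, converged = fj$converged,
                 n_iter = fj$n_iter, config = config,
                 data = list(sample_ids = fj$sample_ids,
                             taxon_ids = fj$taxon_ids,
                             covariate = fj$covariate),
                 diagnostics = fj$diagnostics),
            class = "zippca_fit")
}
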