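#' Construct a genotype table
#'
#' A genotype table is the central data container of the pipeline: an
#' `n x p` integer matrix of genotype codes with one row per sample and one
#' column per SNP. Codes follow the additive dummy convention used throughout:
#' 1 = major homozygous, 2 = heterozygous, 3 = minor homozygous. Missing
#' genotypes are stored as `NA` and must be imputed (see [impute_missing()])
#' before any model fitting.
#'
#' @param codes integer matrix, entries in `{1, 2, 3}` or `NA`.
#' @param sample_ids character vector of unique sample labels, length `nrow(codes)`.
#' @param snp_ids character vector of unique SNP labels, length `ncol(codes)`.
#' @return An object of class `genotype_table`: the validated integer matrix
#'   with `sample_ids` as rownames and `snp_ids` as colnames.
#' @examples
#' g <- genotype_table(matrix(c(1L, 2L, 3L, 1L), 2, 2),
#'                     sample_ids = c("s1", "s2"), snp_ids = c("rs1", "rs2"))
#' @export
genotype_table <- function(codes, sample_ids = rownames(codes),
                           snp_ids = colnames(codes)) {
  if (!is.matrix(codes)) codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(codes)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(codes)))
  sample_ids <- as.character(sample_ids)
  snp_ids <- as.character(snp_ids)
  if (length(sample_ids) != nrow(codes))
    stop("length(sample_ids) must equal nrow(codes)", call. = FALSE)
  if (length(snp_ids) != ncol(codes))
    stop("length(snp_ids) must equal ncol(codes)", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(snp_ids))
    stop("duplicate SNP ids: ",
         paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.na(codes) & !(codes %in% c(1L, 2L, 3L)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "invalid genotype code %s at sample '%s', SNP '%s' (codes must be 1, 2 or 3)",
      codes[bad[1, 1], bad[1, 2]], sample_ids[bad[1, 1]], snp_ids[bad[1, 2]]),
      call. = FALSE)
  }
  dimnames(codes) <- list(sample_ids, snp_ids)
  structure(codes, class = c("genotype_table", "matrix", "array"))
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d samples x %d SNPs (%d missing cells)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

# strip the class so downstream matrix algebra sees a plain integer matrix
as_code_matrix <- function(g) {
  unclass(g)[, , drop = FALSE]
}

#' Read a genotype/phenotype/covariate dataset from delimited text
#'
#' Reads a rectangular CSV/TSV with a header row: one row per sample, one
#' column per SNP plus named phenotype and (optional) covariate columns.
#' Every column not named as a phenotype, covariate or sample-id column is
#' treated as a SNP column and validated against the 1/2/3 coding. Empty
#' cells and the literal `NA` are accepted as missing genotype markers.
#' Samples with a missing phenotype value are dropped (with a message) along
#' with their genotype rows, so the returned structures are always aligned.
#'
#' @param path path to a `.csv` (comma) or `.tsv`/`.txt` (tab) file.
#' @param phenotype_names character vector naming the phenotype column(s).
#' @param covariate_names character vector naming numeric covariate columns.
#' @param sample_id_col optional name of a sample-identifier column; if `NULL`
#'   samples are labelled `sample1..n` in file order.
#' @param sep field separator; guessed from the file extension by default.
#' @return A list with elements `genotypes` ([genotype_table]), `phenotypes`
#'   (named list of numeric vectors, one per phenotype name) and `covariates`
#'   (numeric matrix with one column per covariate, or `NULL`).
#' @export
read_dataset <- function(path, phenotype_names, covariate_names = character(),
                         sample_id_col = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  header <- names(raw)
  missing_cols <- setdiff(c(phenotype_names, covariate_names, sample_id_col), header)
  if (length(missing_cols) > 0)
    stop("column(s) not found in header: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  sample_ids <- if (!is.null(sample_id_col)) raw[[sample_id_col]]
                else paste0("sample", seq_len(nrow(raw)))

  num_col <- function(column, name, kind) {
    vals <- trimws(column)
    vals[vals == "" | vals == "NA"] <- NA
    out <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(out))
    if (length(bad) > 0)
      stop(sprintf("malformed numeric value '%s' in %s column '%s', row %d",
                   vals[bad[1]], kind, name, bad[1]), call. = FALSE)
    out
  }

  phenotypes <- lapply(phenotype_names, function(nm) num_col(raw[[nm]], nm, "phenotype"))
  names(phenotypes) <- phenotype_names
  covariates <- NULL
  if (length(covariate_names) > 0) {
    covariates <- vapply(covariate_names, function(nm)
      num_col(raw[[nm]], nm, "covariate"), numeric(nrow(raw)))
    covariates <- matrix(covariates, nrow = nrow(raw),
                         dimnames = list(NULL, covariate_names))
  }

  snp_names <- setdiff(header, c(phenotype_names, covariate_names, sample_id_col))
  if (length(snp_names) == 0) stop("no SNP columns found", call. = FALSE)
  codes <- vapply(snp_names, function(nm) num_col(raw[[nm]], nm, "genotype"),
                  numeric(nrow(raw)))
  codes <- matrix(codes, nrow = nrow(raw), dimnames = list(NULL, snp_names))
  frac <- which(!is.na(codes) & codes != round(codes), arr.ind = TRUE)
  if (nrow(frac) > 0)
    stop(sprintf("non-integer genotype value %s in SNP '%s', row %d",
                 codes[frac[1, 1], frac[1, 2]], snp_names[frac[1, 2]], frac[1, 1]),
         call. = FALSE)

  # drop samples whose phenotype is missing, keeping structures aligned
  pheno_missing <- Reduce(`|`, lapply(phenotypes, is.na))
  if (any(pheno_missing)) {
    message(sum(pheno_missing), " sample(s) dropped for missing phenotype values")
    keep <- !pheno_missing
    codes <- codes[keep, , drop = FALSE]
    sample_ids <- sample_ids[keep]
    phenotypes <- lapply(phenotypes, function(v) v[keep])
    if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
  }

  n_missing <- sum(is.na(codes))
  if (n_missing > 0)
    message(n_missing, " missing genotype cell(s) loaded; impute before fitting")

  list(genotypes = genotype_table(codes, sample_ids, colnames(codes)),
       phenotypes = phenotypes, covariates = covariates)
}

#' Impute missing genotypes by per-SNP modal code
#'
#' Replaces each missing genotype with the most frequent code observed for
#' that SNP across samples. Ties between modal codes break toward the smaller
#' code (deterministic, and in practice favouring the major-allele class).
#' Non-missing cells are never altered.
#'
#' @param g a [genotype_table].
#' @return A [genotype_table] with no missing cells.
#' @export
impute_missing <- function(g) {
  stopifnot(inherits(g, "genotype_table"))
  codes <- as_code_matrix(g)
  miss_cols <- which(colSums(is.na(codes)) > 0)
  for (j in miss_cols) {
    col <- codes[, j]
    obs <- col[!is.na(col)]
    if (length(obs) == 0)
      stop("SNP '", colnames(codes)[j], "' has no observed genotypes; cannot impute",
           call. = FALSE)
    tab <- tabulate(obs, nbins = 3L)
    mode_code <- which.max(tab)   # which.max returns the first (smallest) tie
    codes[is.na(col), j] <- mode_code
  }
  genotype_table(codes, rownames(codes), colnames(codes))
}

#' Write all pipeline report tables to a directory
#'
#' Serialises a consensus report (see [run_pipeline()]) to plain TSV tables
#' plus a JSON run manifest: per-iteration forest metrics, per-method
#' significant calls with p-values, the final vote matrix, the long-format
#' cross-iteration frequency table, confidence scores, the key-SNP list and,
#' when covariates were supplied, the covariate significance trace.
#'
#' @param report a `consensus_report` as returned by [run_pipeline()].
#' @param out_dir output directory; created if absent.
#' @return Invisibly, the character vector of files written.
#' @export
write_report_tables <- function(report, out_dir) {
  stopifnot(inherits(report, "consensus_report"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- character(0)
  files <- c(files, wr(report$iteration_metrics, "iteration_metrics.tsv"))
  files <- c(files, wr(report$calls, "method_calls.tsv"))

  vm <- report$vote_matrix
  vm_df <- data.frame(snp_id = rownames(vm),
                      as.data.frame(vm, check.names = FALSE),
                      row.names = NULL, check.names = FALSE)
  files <- c(files, wr(vm_df, "vote_matrix.tsv"))
  files <- c(files, wr(report$frequency, "frequency.tsv"))
  files <- c(files, wr(report$confidence, "confidence.tsv"))
  files <- c(files, wr(report$key_snps, "key_snps.tsv"))
  if (!is.null(report$covariate_trace))
    files <- c(files, wr(report$covariate_trace, "covariate_trace.tsv"))

  manifest <- list(config = report$config,
                   seed = report$config$seed,
                   n_samples = report$n_samples,
                   n_snps = report$n_snps,
                   phenotype = report$phenotype_name,
                   package_version = as.character(utils::packageVersion("snpconsensus")),
                   r_version = R.version.string,
                   elapsed_seconds = report$elapsed_seconds,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  manifest_path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(files, manifest_path))
}
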