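test_that("a toy CSV round-trips into aligned genotype/phenotype structures", {
  dir <- withr::local_tempdir()
  codes <- matrix(c(1L, 2L, 3L, 1L,
                    2L, 2L, 1L, 3L,
                    3L, 1L, 1L, 2L), nrow = 4,
                  dimnames = list(NULL, c("rs1", "rs2", "rs3")))
  pheno <- c(0.5, -1.2, 0.3, 2.0)
  path <- write_toy_csv(dir, codes, pheno)

  d <- read_dataset(path, phenotype_names = "pheno", sample_id_col = "sample")
  expect_s3_class(d$genotypes, "genotype_table")
  expect_identical(dim(d$genotypes), c(4L, 3L))
  expect_identical(colnames(d$genotypes), c("rs1", "rs2", "rs3"))
  expect_identical(unname(as.integer(d$genotypes)), as.integer(codes))
  expect_equal(d$phenotypes$pheno, pheno)
  expect_null(d$covariates)
})

test_that("invalid genotype codes and malformed cells are rejected with locations", {
  dir <- withr::local_tempdir()
  codes <- matrix(c(1L, 4L, 2L, 2L, 1L, 3L), nrow = 2,
                  dimnames = list(NULL, c("rs1", "rs2", "rs3")))
  path <- write_toy_csv(dir, codes, c(0.1, 0.2))
  expect_error(read_dataset(path, "pheno", sample_id_col = "sample"),
               "invalid genotype code 4.*rs1")

  writeLines(c("sample,pheno,rs1", "s1,0.1,1", "s2,0.2,oops"),
             file.path(dir, "bad.csv"))
  expect_error(read_dataset(file.path(dir, "bad.csv"), "pheno",
                            sample_id_col = "sample"),
               "malformed numeric value 'oops'.*rs1.*row 2")

  expect_error(genotype_table(matrix(1L, 2, 2), c("a", "b"), c("rs1", "rs1")),
               "duplicate SNP ids")
})

test_that("missing genotype markers load as NA and are counted", {
  dir <- withr::local_tempdir()
  writeLines(c("sample,pheno,rs1,rs2",
               "s1,0.1,1,2", "s2,0.2,,3", "s3,-0.4,NA,1"),
             file.path(dir, "miss.csv"))
  expect_message(
    d <- read_dataset(file.path(dir, "miss.csv"), "pheno",
                      sample_id_col = "sample"),
    "2 missing genotype cell")
  expect_identical(unname(unclass(d$genotypes)[, "rs1"]), c(1L, NA, NA))
  expect_identical(unname(unclass(d$genotypes)[, "rs2"]), c(2L, 3L, 1L))
})

test_that("samples with missing phenotypes are dropped with their genotype rows", {
  dir <- withr::local_tempdir()
  writeLines(c("sample,pheno,rs1", "s1,0.1,1", "s2,,2", "s3,0.3,3"),
             file.path(dir, "drop.csv"))
  expect_message(
    d <- read_dataset(file.path(dir, "drop.csv"), "pheno",
                      sample_id_col = "sample"),
    "1 sample\\(s\\) dropped")
  expect_identical(nrow(d$genotypes), 2L)
  expect_equal(d$phenotypes$pheno, c(0.1, 0.3))
  expect_identical(rownames(d$genotypes), c("s1", "s3"))
})

test_that("modal imputation fills gaps, breaks ties toward the smaller code, and is identity without gaps", {
  g <- genotype_table(matrix(c(1L, 1L, 2L, NA), 4, 1), snp_ids = "rs1")
  expect_identical(unname(as.integer(impute_missing(g))), c(1L, 1L, 2L, 1L))

  tie <- genotype_table(matrix(c(1L, 1L, 2L, 2L, NA), 5, 1), snp_ids = "rs1")
  expect_identical(unname(as.integer(impute_missing(tie))), c(1L, 1L, 2L, 2L, 1L))

  full <- genotype_table(matrix(c(3L, 2L, 1L, 2L), 2, 2))
  expect_identical(impute_missing(full), full)

  empty <- genotype_table(matrix(NA_integer_, 3, 1), snp_ids = "rsX")
  expect_error(impute_missing(empty), "rsX")
})

test_that("imputation never alters observed cells and leaves no missing cells", {
  set.seed(42)
  for (rep in 1:10) {
    codes <- matrix(sample(c(1:3, NA), 60, replace = TRUE,
                           prob = c(0.4, 0.3, 0.2, 0.1)), 10, 6)
    # ensure each column keeps at least one observation
    codes[1, ] <- sample(1:3, 6, replace = TRUE)
    g <- genotype_table(codes)
    gi <- impute_missing(g)
    obs <- !is.na(codes)
    expect_identical(unclass(gi)[obs], codes[obs])
    expect_false(anyNA(gi))
  }
})

test_that("report tables round-trip through the TSV writer", {
  d <- simulate_with_effects(
    simulation_spec(80, 25, maf = 0.3, causal = c(3, 17), beta = c(1, 1),
                    noise_sd = 0.5, seed = 2))
  cfg <- pipeline_config(ntree_schedule = c(60, 80), k = 8,
                         boruta_max_runs = 15, seed = 3)
  rep <- run_pipeline(d$genotypes, d$phenotype, config = cfg)
  dir <- withr::local_tempdir()
  files <- write_report_tables(rep, dir)
  expect_true(all(file.exists(files)))

  key_back <- utils::read.delim(file.path(dir, "key_snps.tsv"))
  expect_equal(key_back$snp_id, rep$key_snps$snp_id)
  expect_equal(key_back$confidence, rep$key_snps$confidence)
  calls_back <- utils::read.delim(file.path(dir, "method_calls.tsv"))
  expect_equal(nrow(calls_back), nrow(rep$calls))
  vm_back <- utils::read.delim(file.path(dir, "vote_matrix.tsv"))
  expect_equal(vm_back$snp_id, rownames(rep$vote_matrix))
  manifest <- jsonlite::read_json(file.path(dir, "run_manifest.json"))
  expect_equal(manifest$seed, 3)

  # an empty key-SNP report writes a header-only file
  null_rep <- rep
  null_rep$key_snps <- rep$key_snps[0, , drop = FALSE]
  dir2 <- withr::local_tempdir()
  write_report_tables(null_rep, dir2)
  key_lines <- readLines(file.path(dir2, "key_snps.tsv"))
  expect_length(key_lines, 1)
})
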