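# Shared fixtures, built in code at test time.

# n x p design with orthonormal, column-centred columns: centring leaves it
# unchanged and X'X = I, so ridge/lasso closed forms apply exactly.
orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  m <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  q <- qr.Q(qr(m))
  colnames(q) <- paste0("X", seq_len(p))
  q
}

# small dense random design for regression oracles
random_design <- function(n, p, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- paste0("X", seq_len(p))
  x
}

# write a toy genotype CSV and return its path
write_toy_csv <- function(dir, codes, phenotype, extra = list()) {
  df <- data.frame(sample = paste0("s", seq_len(nrow(codes))))
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df$pheno <- phenotype
  df <- cbind(df, as.data.frame(codes))
  path <- file.path(dir, "toy.csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}
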