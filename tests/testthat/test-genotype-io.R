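test_that("tabular parsing flags missing calls and preserves dosages", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tmA\tmB",
               "s1\t0\t2",
               "s2\t1\tNA",
               "s3\t2\t0.5"), path)
  m <- read_snp_matrix(path)
  expect_equal(m$samples, c("s1", "s2", "s3"))
  expect_equal(sum(missing_mask(m)), 1L)
  expect_true(is.na(m$dosages["s2", "mB"]))
  expect_equal(m$dosages["s3", "mB"], 0.5)
})

test_that("VCF GT codes map to ALT-allele dosages and multi-allelic records are rejected", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
               "1\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
               "1\t200\tsnp2\tC\tT\t.\tPASS\t.\tGT\t./.\t0|1\t1/1"),
             path)
  m <- read_snp_matrix(path)
  expect_equal(unname(m$dosages[, "snp1"]), c(0, 1, 2))
  expect_equal(unname(m$dosages[, "snp2"]), c(NA, 1, 2))
  expect_equal(m$markers$pos, c(100L, 200L))

  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "s1"), collapse = "\t"),
               "1\t100\tsnpX\tA\tG,T\t.\tPASS\t.\tGT\t0/1"), bad)
  expect_error(read_snp_matrix(bad), "snpX")
})

test_that("write/read round-trips preserve dosages and missingness in both dialects", {
  d <- matrix(sample(c(0:2, NA), 200, replace = TRUE, prob = c(.3, .3, .3, .1)),
              10, 20)
  storage.mode(d) <- "double"
  m <- snp_fix(d)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_snp_matrix(m, tsv)
  expect_equal(read_snp_matrix(tsv)$dosages, m$dosages)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_snp_matrix(m, vcf, format = "vcf")
  expect_equal(read_snp_matrix(vcf)$dosages, m$dosages)
})

test_that("MAF matches hand counts and is orientation-invariant", {
  m <- snp_fix(cbind(c(0, 0, 0, 0), c(0, 1, 2, 1), c(2, 2, 2, 0)))
  maf <- minor_allele_frequency(m)
  expect_equal(unname(maf), c(0, 0.5, 0.25))
  flipped <- snp_fix(2 - m$dosages)
  expect_equal(minor_allele_frequency(flipped), maf)
  # missing calls excluded from the denominator
  m2 <- snp_fix(matrix(c(0, 2, NA), ncol = 1))
  expect_equal(unname(minor_allele_frequency(m2)), 0.5)
  m3 <- snp_fix(matrix(c(NA_real_, NA_real_), ncol = 1))
  expect_error(minor_allele_frequency(m3), "missing")
})

test_that("MAF filter keeps the >= boundary and refuses to empty the panel", {
  # MAFs: 0, 0.04 (1/25), 0.05 (1/20), 0.2, 0.5
  n <- 50
  d <- cbind(rep(0, n),
             c(rep(1, 4), rep(0, n - 4)),
             c(rep(1, 5), rep(0, n - 5)),
             c(rep(1, 20), rep(0, n - 20)),
             c(rep(1, n)))
  m <- snp_fix(d)
  expect_equal(unname(minor_allele_frequency(m)),
               c(0, 0.04, 0.05, 0.2, 0.5))
  kept <- filter_maf(m, 0.05)
  expect_equal(ncol(kept$dosages), 3L)
  expect_equal(kept$samples, m$samples)
  expect_equal(ncol(filter_maf(m, 0)$dosages), 5L)  # threshold 0 is a no-op
  expect_error(filter_maf(snp_fix(matrix(rep(0, 4), 2)), 0.1), "every marker")
})

test_that("marker count after MAF filtering is monotone non-increasing in threshold", {
  m <- impute_missing(snp_fix(rand_dosages(40, 200, seed = 7, maf = c(0.01, 0.99))))
  counts <- vapply(c(0, 0.02, 0.05, 0.1, 0.2, 0.3),
                   function(th) ncol(filter_maf(m, th)$dosages), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("imputation fills per method and never alters observed calls", {
  d <- cbind(c(0, 2, NA, 2), c(0, 0, 2, NA), c(1, 1, 1, 1))
  m <- snp_fix(d)
  for (meth in c("marker_mean", "marker_mode", "knn")) {
    out <- impute_missing(m, method = meth)
    expect_false(anyNA(out$dosages))
    obs <- !is.na(d)
    expect_equal(out$dosages[obs], d[obs])
  }
  expect_equal(impute_missing(m, "marker_mean")$dosages[3, 1], 4 / 3)
  expect_equal(impute_missing(m, "marker_mode")$dosages[4, 2], 0)
  # mean imputation of (0, 2, NA) gives 1.0
  m2 <- snp_fix(matrix(c(0, 2, NA), ncol = 1))
  expect_equal(impute_missing(m2, "marker_mean")$dosages[3, 1], 1.0)
  # fully observed input returned unchanged by every method
  full <- snp_fix(cbind(c(0, 1), c(2, 1)))
  for (meth in c("marker_mean", "marker_mode", "knn"))
    expect_equal(impute_missing(full, method = meth)$dosages, full$dosages)
  expect_error(impute_missing(m, method = "hmm"))
})

test_that("knn imputation borrows from the nearest samples", {
  # two tight groups; the missing cell should take its group's dosage
  d <- rbind(c(0, 0, 0, 0, NA), c(0, 0, 0, 0, 0), c(0, 0, 0, 1, 0),
             c(2, 2, 2, 2, 2), c(2, 2, 2, 2, 2), c(2, 2, 1, 2, 2))
  out <- impute_missing(snp_fix(d), "knn", k = 2)
  expect_lt(out$dosages[1, 5], 0.5)
})

test_that("PC scores match a dense eigendecomposition oracle and are centered/orthogonal", {
  m <- impute_missing(snp_fix(rand_dosages(30, 200, seed = 3)))
  k <- 4
  p <- pca_scores(m, k = k)
  expect_equal(unname(colMeans(p$scores)), rep(0, k), tolerance = 1e-8)
  cp <- crossprod(p$scores)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-6)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  # oracle: eigendecomposition of the centered covariance
  X <- scale(m$dosages, scale = FALSE)
  eg <- eigen(tcrossprod(X) / (nrow(X) - 1), symmetric = TRUE)
  scores_oracle <- eg$vectors[, 1:k] %*% diag(sqrt(eg$values[1:k] * (nrow(X) - 1)))
  for (j in 1:k)
    expect_equal(abs(stats::cor(p$scores[, j], scores_oracle[, j])), 1,
                 tolerance = 1e-6)
  expect_error(pca_scores(m, k = 31), "rank")
})

test_that("duplicated-row groups collapse to two distinct PC1 scores", {
  base <- rand_dosages(2, 50, seed = 9)
  d <- rbind(base[rep(1, 5), ], base[rep(2, 5), ])
  rownames(d) <- sprintf("s%02d", 1:10)
  p <- pca_scores(snp_fix(d), k = 2)
  vals <- round(p$scores[, 1], 8)
  expect_equal(length(unique(vals)), 2L)
  expect_equal(length(unique(vals[1:5])), 1L)
})

test_that("PCA applies the documented deterministic sign convention", {
  m <- impute_missing(snp_fix(rand_dosages(20, 60, seed = 5)))
  p1 <- pca_scores(m, k = 2)
  expect_identical(p1$scores, pca_scores(m, k = 2)$scores)
  # oracle: prcomp scores oriented so the largest-|loading| is positive
  pc <- stats::prcomp(m$dosages, center = TRUE, rank. = 2)
  for (j in 1:2) {
    l <- pc$rotation[, j]
    flip <- sign(l[which.max(abs(l))])
    expect_equal(unname(p1$scores[, j]), unname(flip * pc$x[, j]),
                 tolerance = 1e-10)
  }
})
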