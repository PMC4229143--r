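#' SNP dosage matrix
#'
#' Container for a biallelic SNP panel scored as allele dosages in \[0, 2\]
#' (counts of the tracked allele; real-valued dosages are allowed so that
#' GBS calls from mixed-ploidy material collapsed to diploidized dosages,
#' and mean-imputed values, are representable). Missing calls are stored as
#' `NA` in the dosage matrix; [missing_mask()] exposes them as a logical
#' matrix.
#'
#' @param dosages numeric matrix, samples in rows, markers in columns.
#'   Entries must be in \[0, 2\] or `NA`. Row names are sample identifiers,
#'   column names marker identifiers; both must be unique.
#' @param markers optional data.frame of marker metadata with columns `id`
#'   and optionally `chrom` and `pos` (1-based). Defaults to the column
#'   names of `dosages`.
#'
#' @return An object of class `snp_matrix` with elements `dosages`,
#'   `samples`, `markers`.
#' @export
snp_matrix <- function(dosages, markers = NULL) {
  if (!is.matrix(dosages) || !is.numeric(dosages))
    stop("`dosages` must be a numeric matrix")
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    stop("`dosages` must carry sample row names and marker column names")
  if (anyDuplicated(rownames(dosages)))
    stop("duplicated sample identifiers")
  if (anyDuplicated(colnames(dosages)))
    stop("duplicated marker identifiers")
  rng <- suppressWarnings(range(dosages, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("non-missing dosages must lie in [0, 2]")
  if (is.null(markers)) {
    markers <- data.frame(id = colnames(dosages),
                          chrom = NA_character_, pos = NA_integer_,
                          stringsAsFactors = FALSE)
  } else {
    if (!all(markers$id == colnames(dosages)))
      stop("marker metadata ids must match dosage column names in order")
  }
  structure(list(dosages = dosages,
                 samples = rownames(dosages),
                 markers = markers),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  n_miss <- sum(is.na(x$dosages))
  cat(sprintf("snp_matrix: %d samples x %d markers (%d missing calls, %.2f%%)\n",
              nrow(x$dosages), ncol(x$dosages), n_miss,
              100 * n_miss / length(x$dosages)))
  invisible(x)
}

#' @export
dim.snp_matrix <- function(x) dim(x$dosages)

#' Logical mask of missing genotype calls
#'
#' @param m a [snp_matrix]
#' @return logical matrix, `TRUE` where the call is absent.
#' @export
missing_mask <- function(m) {
  stopifnot(inherits(m, "snp_matrix"))
  is.na(m$dosages)
}

#' Read a SNP dosage matrix
#'
#' Reads either a VCF (v4.x, GT field, biallelic SNP records, missing calls
#' `./.`) or the package's tabular dosage dialect: a TSV whose header row
#' holds marker ids, whose first column (`sample_id`) holds sample ids, and
#' whose cells are dosages in \[0, 2\] (decimals allowed) or `NA`.
#' Dosages are oriented so that column mean / 2 is the frequency of the
#' counted allele (for VCF, the ALT allele).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vcf"`, or `"tabular"`.
#' @return a [snp_matrix]; missing calls are flagged `NA`, never zero-filled.
#' @export
read_snp_matrix <- function(path, format = c("auto", "vcf", "tabular")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tabular"
  if (format == "vcf") read_snp_vcf(path) else read_snp_tabular(path)
}

read_snp_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) stop("parse error: no variant records in ", path)
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    bad <- fix[multi, "ID"]
    bad[is.na(bad) | bad == "."] <- paste0(fix[multi, "CHROM"], ":",
                                           fix[multi, "POS"])[is.na(bad) | bad == "."]
    stop("multi-allelic VCF record(s) rejected: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  # dosage = number of ALT alleles; "." or "./." -> NA
  count_alt <- function(g) {
    out <- rep(NA_real_, length(g))
    ok <- !is.na(g) & !grepl("\\.", g)
    alleles <- strsplit(gsub("\\|", "/", g[ok]), "/", fixed = FALSE)
    out[ok] <- vapply(alleles, function(a) sum(a != "0"), numeric(1))
    out
  }
  dos <- t(apply(gt, 1, count_alt))
  colnames(dos) <- colnames(gt)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  dos <- t(dos)           # samples x markers
  colnames(dos) <- ids
  markers <- data.frame(id = ids, chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        stringsAsFactors = FALSE)
  snp_matrix(dos, markers)
}

read_snp_tabular <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ""), data.table = FALSE)
  if (ncol(dt) < 2) stop("parse error in ", path, ": need sample_id + markers")
  samples <- as.character(dt[[1]])
  num <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(num)) {
    bad <- which(apply(dt[, -1, drop = FALSE], 2,
                       function(z) any(!is.na(z) & is.na(suppressWarnings(as.numeric(z))))))
    stop("parse error in ", path, ": non-numeric dosage in column(s) ",
         paste(names(bad), collapse = ", "))
  }
  storage.mode(num) <- "double"
  rownames(num) <- samples
  snp_matrix(num)
}

#' Write a SNP dosage matrix
#'
#' `tabular` writes the TSV dialect read by [read_snp_matrix()]. `vcf`
#' writes a minimal VCF v4.2 with GT-only genotypes and requires integer
#' dosages (0/1/2 or missing).
#'
#' @param m a [snp_matrix]
#' @param path output file path
#' @param format `"tabular"` or `"vcf"`
#' @return `path`, invisibly.
#' @export
write_snp_matrix <- function(m, path, format = c("tabular", "vcf")) {
  stopifnot(inherits(m, "snp_matrix"))
  format <- match.arg(format)
  if (format == "tabular") {
    df <- data.frame(sample_id = m$samples, m$dosages,
                     check.names = FALSE, stringsAsFactors = FALSE)
    data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  } else {
    d <- m$dosages
    if (any(!is.na(d) & d != round(d)))
      stop("VCF output requires integer dosages; impute/round first or use tabular")
    gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    chrom <- m$markers$chrom
    chrom[is.na(chrom)] <- "1"
    pos <- m$markers$pos
    pos[is.na(pos)] <- seq_len(ncol(d))[is.na(pos)]
    lines <- c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", m$samples), collapse = "\t"))
    body <- vapply(seq_len(ncol(d)), function(j) {
      g <- d[, j]
      gs <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
      paste(c(chrom[j], pos[j], m$markers$id[j], "A", "T", ".", "PASS", ".",
              "GT", gs), collapse = "\t")
    }, character(1))
    writeLines(c(lines, body), path)
  }
  invisible(path)
}

#' Per-marker minor allele frequency
#'
#' For each marker, the counted-allele frequency is
#' `p = sum(non-missing dosages) / (2 * n non-missing)`; the minor allele
#' frequency is `min(p, 1 - p)`, so the result is orientation-free.
#'
#' @param m a [snp_matrix]
#' @return named numeric vector of MAFs in \[0, 0.5\].
#' @export
minor_allele_frequency <- function(m) {
  stopifnot(inherits(m, "snp_matrix"))
  n_obs <- colSums(!is.na(m$dosages))
  if (any(n_obs == 0))
    stop("marker(s) with all calls missing: ",
         paste(utils::head(m$markers$id[n_obs == 0], 5), collapse = ", "))
  p <- colSums(m$dosages, na.rm = TRUE) / (2 * n_obs)
  maf <- pmin(p, 1 - p)
  names(maf) <- m$markers$id
  maf
}

#' Remove low-frequency markers
#'
#' Retains exactly the markers with MAF >= `threshold` (boundary kept);
#' sample set and marker order are unchanged.
#'
#' @param m a [snp_matrix]
#' @param threshold MAF threshold in \[0, 0.5\].
#' @return the filtered [snp_matrix].
#' @export
filter_maf <- function(m, threshold = 0.05) {
  stopifnot(inherits(m, "snp_matrix"))
  if (threshold < 0 || threshold > 0.5)
    stop("`threshold` must lie in [0, 0.5]")
  keep <- minor_allele_frequency(m) >= threshold
  if (!any(keep))
    stop("MAF filter at ", threshold, " removed every marker")
  snp_matrix(m$dosages[, keep, drop = FALSE],
             m$markers[keep, , drop = FALSE])
}

#' Impute missing genotype calls
#'
#' `marker_mean` fills each missing call with the column mean of the
#' non-missing dosages (preserves the marker's allele frequency);
#' `marker_mode` with the most frequent rounded dosage class; `knn` with the
#' mean dosage over the `k` nearest samples by Euclidean distance on shared
#' non-missing markers (falling back to the marker mean when no neighbour
#' carries a call). Non-missing entries are never altered.
#'
#' @param m a [snp_matrix]; every marker needs at least one non-missing call.
#' @param method imputation method.
#' @param k neighbour count for `knn`.
#' @param rng_seed seed controlling neighbour tie-breaks for `knn`.
#' @return a fully observed [snp_matrix].
#' @export
impute_missing <- function(m, method = c("marker_mean", "marker_mode", "knn"),
                           k = 5, rng_seed = 1L) {
  stopifnot(inherits(m, "snp_matrix"))
  method <- match.arg(method)
  d <- m$dosages
  n_obs <- colSums(!is.na(d))
  if (any(n_obs == 0))
    stop("cannot impute marker(s) with no observed calls: ",
         paste(utils::head(m$markers$id[n_obs == 0], 5), collapse = ", "))
  if (!anyNA(d)) return(m)
  if (method == "marker_mean") {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  } else if (method == "marker_mode") {
    modes <- apply(d, 2, function(col) {
      tab <- table(round(col[!is.na(col)]))
      as.numeric(names(tab)[which.max(tab)])
    })
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- modes[idx[, 2]]
  } else {
    d <- withr::with_seed(rng_seed, impute_knn(d, k))
  }
  out <- m
  out$dosages <- d
  out
}

impute_knn <- function(d, k) {
  n <- nrow(d)
  need <- which(rowSums(is.na(d)) > 0)
  filled <- d
  for (i in need) {
    shared_dist <- vapply(seq_len(n), function(j) {
      if (j == i) return(Inf)
      ok <- !is.na(d[i, ]) & !is.na(d[j, ])
      if (!any(ok)) return(Inf)
      sqrt(mean((d[i, ok] - d[j, ok])^2))   # per-marker scale: comparable at unequal overlap
    }, numeric(1))
    ord <- order(shared_dist, stats::runif(n))  # seeded tie-break
    nb <- ord[seq_len(min(k, sum(is.finite(shared_dist))))]
    miss <- which(is.na(d[i, ]))
    for (j in miss) {
      vals <- d[nb, j]
      filled[i, j] <- if (all(is.na(vals))) mean(d[, j], na.rm = TRUE)
                      else mean(vals, na.rm = TRUE)
    }
  }
  filled
}

#' Principal components of the dosage matrix
#'
#' Computes sample scores of the top `k` principal components of the
#' column-centered (optionally unit-variance-scaled) dosage matrix, for use
#' as population-structure covariates. Sign convention: within each
#' component the loading of largest magnitude is positive.
#'
#' @param m a fully imputed [snp_matrix].
#' @param k number of components (`k <= min(n_samples - 1, n_markers)`).
#' @param scale. scale markers to unit variance before decomposition?
#'   Default `FALSE` (centering only), the common GBS convention.
#' @return an object of class `pc_scores`: list with `samples`, `scores`
#'   (n x k), `explained_variance` (fractions, non-increasing).
#' @export
pca_scores <- function(m, k = 2, scale. = FALSE) {
  stopifnot(inherits(m, "snp_matrix"))
  if (anyNA(m$dosages))
    stop("dosage matrix has missing calls; run impute_missing() first")
  max_k <- min(nrow(m$dosages) - 1L, ncol(m$dosages))
  if (k > max_k)
    stop("k = ", k, " exceeds the available rank (", max_k, ")")
  d <- m$dosages
  if (scale.) {
    sds <- apply(d, 2, stats::sd)
    d <- d[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(d, center = TRUE, scale. = scale., rank. = k)
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  rownames(scores) <- m$samples
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(samples = m$samples,
                 scores = scores,
                 explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]),
            class = "pc_scores")
}

#' @export
print.pc_scores <- function(x, ...) {
  cat(sprintf("pc_scores: %d samples x %d components (%.1f%% variance)\n",
              length(x$samples), ncol(x$scores),
              100 * sum(x$explained_variance)))
  invisible(x)
}

#' Write principal-component scores as CSV
#'
#' @param p a `pc_scores` object
#' @param path output CSV path
#' @return `path`, invisibly.
#' @export
write_pc_scores <- function(p, path) {
  df <- data.frame(sample_id = p$samples, p$scores, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
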