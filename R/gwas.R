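# Single-marker association mapping of network indices. The model is ordinary
# least squares of the log-transformed phenotype on a 0/1 genotype indicator
# (plus optional structure covariates via Frisch-Waugh-Lovell
# residualization), with a two-sided t-test on the genetic effect.

#' Filter SNPs by minor allele frequency
#'
#' Retains SNPs with \code{min(freq, 1 - freq) > min_maf}, frequencies
#' computed on non-missing calls. All-missing SNPs are dropped with a
#' warning.
#'
#' @param G Hosts x SNPs matrix of 0/1/NA.
#' @param min_maf Strict lower bound on MAF (default 0.05).
#' @return Filtered matrix; attribute \code{maf} carries retained MAFs.
#' @export
maf_filter <- function(G, min_maf = 0.05) {
  freq <- colMeans(G, na.rm = TRUE)
  all_missing <- colSums(!is.na(G)) == 0
  if (any(all_missing)) {
    warning(sprintf("%d all-missing SNPs dropped", sum(all_missing)))
  }
  maf <- pmin(freq, 1 - freq)
  keep <- !all_missing & !is.na(maf) & maf > min_maf
  out <- G[, keep, drop = FALSE]
  attr(out, "maf") <- maf[keep]
  out
}

# per-SNP mean imputation; drops SNPs with > max_missing fraction missing
.impute_genotypes <- function(G, max_missing = 0.10) {
  miss_frac <- colMeans(is.na(G))
  keep <- miss_frac <= max_missing
  G <- G[, keep, drop = FALSE]
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  G
}

#' Log transform for network-index phenotypes
#'
#' \code{log10(index + 1e-6)}: indices can be exactly 0 (empty networks), so
#' a small fixed offset keeps the transform finite.
#' @param y Numeric vector of index values.
#' @param offset Offset added before log10.
#' @return Transformed vector.
#' @export
log_phenotype <- function(y, offset = 1e-6) log10(y + offset)

#' Per-SNP linear association scan
#'
#' For each SNP, fits \code{y = mu + x beta + e} by OLS (0 = high-frequency
#' allele, 1 = low-frequency allele) and reports the two-sided t-test p-value
#' on beta. Missing genotypes are mean-imputed (SNPs > 10\% missing dropped).
#' Covariates (e.g. subpopulation membership proportions, Q-model) are
#' projected out of phenotype and genotypes first; the residual test is the
#' exact partial t-test of the joint fit.
#'
#' @param y Phenotype vector, already log-transformed, named by host or
#'   aligned to \code{G}'s rows.
#' @param G Hosts x SNPs genotype matrix.
#' @param covariates Optional hosts x q numeric matrix.
#' @return data.frame: snp, beta, se, t, p_value, maf, n_used. SNPs with zero
#'   genotype variance after imputation are reported with NA statistics and
#'   listed in the \code{skipped} attribute.
#' @export
associate <- function(y, G, covariates = NULL) {
  n <- length(y)
  if (n != nrow(G)) stop("phenotype and genotypes must align")
  if (n < 3) stop("need at least 3 hosts")
  if (!all(is.finite(y))) stop("phenotype must be finite after log transform")
  G <- .impute_genotypes(G)
  freq <- colMeans(G)
  maf <- pmin(freq, 1 - freq)
  q <- 0L
  X <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    X <- cbind(X, covariates)
    q <- ncol(covariates)
  }
  qr_X <- qr(X)
  y_r <- qr.resid(qr_X, y)
  G_r <- qr.resid(qr_X, G)
  sxx <- colSums(G_r^2)
  sxy <- as.numeric(crossprod(G_r, y_r))
  syy <- sum(y_r^2)
  if (syy < .Machine$double.eps^0.9 * max(1, sum(y^2))) {
    # phenotype constant after covariate projection: nothing to explain
    sxy[] <- 0
    syy <- 0
  }
  df <- n - 2L - q
  beta <- ifelse(sxx > 1e-12, sxy / sxx, NA_real_)
  rss <- syy - ifelse(is.na(beta), 0, beta^2 * sxx)
  rss <- pmax(rss, 0)
  se <- sqrt(rss / df / sxx)
  se[is.na(beta)] <- NA_real_
  # se = 0 happens for a perfect fit (p -> 0) or a constant phenotype (p = 1)
  tval <- ifelse(!is.na(se) & se > 0, beta / se,
                 ifelse(abs(beta) < 1e-300, 0, Inf))
  tval[is.na(beta)] <- NA_real_
  p <- 2 * stats::pt(-abs(tval), df)
  p[!is.na(p) & p < .Machine$double.xmin] <- .Machine$double.xmin
  p[!is.na(tval) & tval == 0] <- 1
  res <- data.frame(snp = colnames(G), beta = beta, se = se, t = tval,
                    p_value = p, maf = maf, n_used = n,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "skipped") <- res$snp[is.na(beta)]
  attr(res, "df") <- df
  res
}

#' Significant hits at a fixed -log10(p) line
#'
#' Retains SNPs with \code{-log10(p) >= threshold_logp} (inclusive), sorted
#' by p ascending. A Bonferroni-adjusted p column is included for reference.
#'
#' @param res [associate()] result.
#' @param threshold_logp Significance line on the -log10 scale (default 5).
#' @return Subset data.frame with extra columns neg_log10_p, p_bonferroni.
#' @export
significant_hits <- function(res, threshold_logp = 5) {
  ok <- !is.na(res$p_value)
  res <- res[ok, , drop = FALSE]
  res$neg_log10_p <- -log10(res$p_value)
  res$p_bonferroni <- pmin(1, res$p_value * nrow(res))
  hits <- res[res$neg_log10_p >= threshold_logp, , drop = FALSE]
  hits <- hits[order(hits$p_value), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Genomic-control inflation and QQ coordinates
#'
#' lambda_GC is the median observed 1-df chi-square statistic (obtained from
#' the p-values) divided by the median of the chi-square(1) distribution.
#'
#' @param res [associate()] result (or any object with a p_value column).
#' @return List: lambda, and a data.frame \code{qq} of sorted expected vs
#'   observed -log10 p pairs.
#' @export
qq_inflation <- function(res) {
  p <- res$p_value
  p <- p[!is.na(p)]
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
  m <- length(p)
  qq <- data.frame(
    expected = -log10(stats::ppoints(m)),
    observed = -log10(sort(p))
  )
  list(lambda = lambda, qq = qq)
}

#' SNP heritability of a network index
#'
#' Per-SNP h2 is the R-squared of the single-SNP fit; total SNP-h2 is the
#' R-squared of the joint OLS fit on all significant SNPs. When the number of
#' hits approaches the sample size (>= n - 1) the joint fit switches to ridge
#' with a fixed small penalty and is flagged.
#'
#' @param y Log-transformed phenotype vector.
#' @param hits Hit table from [significant_hits()] (needs a snp column).
#' @param G Hosts x SNPs genotype matrix containing the hit SNPs.
#' @return List: per_snp data.frame (snp, h2), total (joint R2, 0 when no
#'   hits), ridge flag.
#' @export
snp_heritability <- function(y, hits, G) {
  if (nrow(hits) == 0) {
    return(list(per_snp = data.frame(snp = character(0), h2 = numeric(0)),
                total = 0, ridge = FALSE))
  }
  Gh <- .impute_genotypes(G[, hits$snp, drop = FALSE], max_missing = 1)
  n <- length(y)
  yc <- y - mean(y)
  tss <- sum(yc^2)
  per <- vapply(seq_len(ncol(Gh)), function(j) {
    x <- Gh[, j] - mean(Gh[, j])
    sxx <- sum(x^2)
    if (sxx < 1e-12 || tss < 1e-12) return(0)
    (sum(x * yc)^2 / sxx) / tss
  }, numeric(1))
  ridge <- ncol(Gh) >= n - 1
  Xc <- scale(Gh, scale = FALSE)
  if (!ridge) {
    fit <- stats::lm.fit(cbind(1, Gh), y)
    r2 <- if (tss < 1e-12) 0 else 1 - sum(fit$residuals^2) / tss
  } else {
    lambda <- 1e-3 * n
    beta <- solve(crossprod(Xc) + diag(lambda, ncol(Xc)), crossprod(Xc, yc))
    r2 <- if (tss < 1e-12) 0 else 1 - sum((yc - Xc %*% beta)^2) / tss
  }
  list(per_snp = data.frame(snp = hits$snp, h2 = per, stringsAsFactors = FALSE),
       total = max(0, min(1, r2)), ridge = ridge)
}

#' Scan every index phenotype against every SNP
#'
#' Convenience wrapper: runs [associate()], [significant_hits()] and
#' [qq_inflation()] for each of the 24 phenotype columns of an index table.
#'
#' @param indices [index_table()] result.
#' @param G Hosts x SNPs genotype matrix (rows matching \code{host_id}).
#' @param covariates Optional covariate matrix.
#' @param min_maf MAF filter bound.
#' @param threshold_logp Significance line.
#' @return Named list per phenotype: result, hits, lambda, heritability.
#' @export
gwas_scan <- function(indices, G, covariates = NULL, min_maf = 0.05,
                      threshold_logp = 5) {
  G <- maf_filter(G[indices$host_id, , drop = FALSE], min_maf)
  phenos <- setdiff(names(indices), "host_id")
  out <- lapply(phenos, function(ph) {
    y <- log_phenotype(indices[[ph]])
    res <- associate(y, G, covariates)
    hits <- significant_hits(res, threshold_logp)
    list(result = res, hits = hits,
         lambda = qq_inflation(res)$lambda,
         heritability = snp_heritability(y, hits, G))
  })
  names(out) <- phenos
  out
}
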