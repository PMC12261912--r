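#' Single-marker association scan with principal-component covariates
#'
#' Per site, least-squares regression of the phenotype on alternate-allele
#' dosage plus the top-m PC scores; the reported p-value is the two-sided t
#' test on the dosage slope. Missing dosages are imputed at the site mean.
#' Binary traits coded 0/1 are handled by the same linear model (at scan scale
#' this is equivalent to the score test). Sites monomorphic after imputation
#' are skipped (`NA` statistics).
#'
#' The per-site fit is computed in closed form after projecting phenotype and
#' dosages off the covariate space (Frisch-Waugh), which makes the scan a few
#' matrix products rather than one `lm()` per site.
#'
#' @param gm A `genotype_matrix`.
#' @param phenotype Numeric vector aligned with `gm$samples` (binary 0/1
#'   allowed); must not be constant.
#' @param model Optional `pca_model` providing covariate scores.
#' @param m_covariates Number of PCs used as covariates (0 = none).
#' @return data.frame: `chrom`, `pos`, `site_id`, `beta`, `stat`, `p`.
#' @export
assoc_scan <- function(gm, phenotype, model = NULL, m_covariates = 0) {
  y <- as.numeric(phenotype)
  n <- length(gm$samples)
  if (length(y) != n) stop("phenotype length must match sample count")
  if (anyNA(y)) stop("phenotype must be complete")
  if (stats::var(y) == 0) stop("constant phenotype")
  covar <- matrix(1, n, 1)
  if (m_covariates > 0) {
    if (is.null(model)) stop("m_covariates > 0 requires a pca_model")
    m <- min(m_covariates, ncol(model$scores))
    covar <- cbind(covar, model$scores[gm$samples, seq_len(m), drop = FALSE])
  }
  Q <- qr.Q(qr(covar))                     # orthonormal basis incl. intercept
  yr <- y - Q %*% crossprod(Q, y)
  d <- gm$dosage
  mu <- rowMeans(d, na.rm = TRUE)
  miss <- is.na(d)
  if (any(miss)) d[miss] <- mu[row(d)[miss]]
  G <- t(d)                                # samples x sites
  Gr <- G - Q %*% crossprod(Q, G)
  gg <- colSums(Gr^2)
  gy <- drop(crossprod(Gr, yr))
  df <- n - ncol(covar) - 1
  beta <- gy / gg
  rss <- drop(sum(yr^2)) - beta^2 * gg
  se <- sqrt(pmax(rss, 0) / df / gg)
  stat <- beta / se
  p <- 2 * stats::pt(-abs(stat), df)
  skip <- gg <= 1e-12 | df < 1
  beta[skip] <- NA; stat[skip] <- NA; p[skip] <- NA
  data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
             site_id = gm$sites$site_id, beta = beta, stat = stat, p = p,
             stringsAsFactors = FALSE)
}

#' Write association results as TSV
#' @param res Output of [assoc_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assoc <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
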