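#' Genotype PCA with the allele-frequency standardization
#'
#' Sites with minor allele frequency 0 are dropped (their scale would be 0).
#' Missing dosages are imputed at the site mean; each site is centered by
#' 2*p and scaled by sqrt(2*p*(1-p)), the binomial-variance convention for
#' dosage data. Scores and loadings come from the top-k singular value
#' decomposition of the samples x sites standardized matrix. Sign convention:
#' the largest-magnitude entry of each loading vector is positive.
#'
#' @param gm A `genotype_matrix` with at least two samples.
#' @param k Number of components; silently truncated to the matrix rank with a
#'   warning if too large.
#' @return A `pca_model`: `site_key`, `center` (2p), `scale`, `loadings`
#'   (sites x k), `scores` (samples x k), `explained` (variance fractions).
#' @export
pca_fit <- function(gm, k = 10) {
  if (length(gm$samples) < 2) stop("PCA needs at least two samples")
  d <- gm$dosage
  n_called <- rowSums(!is.na(d))
  p <- rowSums(d, na.rm = TRUE) / (2 * pmax(n_called, 1))
  poly <- n_called > 0 & p > 0 & p < 1
  d <- d[poly, , drop = FALSE]
  p <- p[poly]
  center <- 2 * p
  scale <- sqrt(2 * p * (1 - p))
  x <- (d - center) / scale
  x[is.na(x)] <- 0                       # mean imputation after centering
  x <- t(x)                              # samples x sites
  rk <- min(dim(x))
  if (k > rk) {
    warning("k reduced to the matrix rank ", rk)
    k <- rk
  }
  sv <- svd(x, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, 1)
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, `*`)
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k),
                  2, flip, `*`)
  rownames(scores) <- gm$samples
  structure(list(site_key = variant_key(gm$sites[poly, , drop = FALSE]),
                 center = center, scale = scale, loadings = loadings,
                 scores = scores, explained = sv$d[seq_len(k)]^2 / sum(sv$d^2),
                 k = k),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d sites, %d samples, k = %d (%.1f%% variance)\n",
              length(x$site_key), nrow(x$scores), x$k, 100 * sum(x$explained)))
  invisible(x)
}

#' Project new samples onto a fitted genotype PCA
#'
#' New dosages are standardized with the *stored* model means and scales
#' (never re-estimated). Model sites missing in a new sample contribute 0
#' after mean imputation, so projecting a sample genotyped at the model means
#' gives the zero vector, and projecting a training sample reproduces its
#' stored score.
#'
#' @param model A `pca_model`.
#' @param new_gm A `genotype_matrix` of new samples covering (a subset of) the
#'   model sites; a sample with under half of the model sites available gets a
#'   warning.
#' @return samples x k score matrix.
#' @export
pca_project <- function(model, new_gm) {
  i <- match(model$site_key, variant_key(new_gm$sites))
  d <- matrix(NA_real_, length(model$site_key), length(new_gm$samples))
  avail <- !is.na(i)
  d[avail, ] <- new_gm$dosage[i[avail], , drop = FALSE]
  frac <- colMeans(!is.na(d))
  low <- frac < 0.5
  if (any(low))
    warning("sample(s) with <50% of model sites available: ",
            paste(new_gm$samples[low], collapse = ", "))
  x <- (d - model$center) / model$scale
  x[is.na(x)] <- 0
  scores <- t(x) %*% model$loadings
  rownames(scores) <- new_gm$samples
  scores
}

#' Write PCA scores as TSV
#' @param scores A score matrix with sample rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  out <- data.frame(sample = rownames(scores), scores, check.names = FALSE)
  colnames(out)[-1] <- paste0("PC", seq_len(ncol(scores)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
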