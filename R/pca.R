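## PCA of a fit panel with least-squares projection of partially missing
## samples onto the inferred principal components.

#' PCA with projection of low-coverage samples
#'
#' The PCA space is built from the `fit_ids` individuals only: SNP-wise
#' centering (and optional `1/sqrt(p(1-p))` scaling) is estimated on the
#' fit panel, missing fit-panel entries are mean-imputed, and the
#' standardized matrix is decomposed by SVD.  Each projected sample is
#' then placed by least squares of its centered genotypes against the
#' SNP loadings restricted to its non-missing SNPs, so heavy missingness
#' shrinks information but never biases through imputation.  A fit-panel
#' member with no missing data projects exactly onto its own score
#' coordinates.
#'
#' @param panel a [genotype_panel()].  Genotypes are used as dosages;
#'   haploid dosages are doubled so haploid and diploid individuals share
#'   a scale.
#' @param fit_ids individuals spanning the space (default: all moderns).
#' @param project_ids individuals to project (default: all non-fit
#'   individuals).
#' @param scale `"none"` (default) or `"unit-variance"`
#'   (`1/sqrt(p(1-p))` SNP scaling with p the fit-panel mean frequency).
#' @param n_pc number of components to keep (default
#'   `min(10, rank bound)`; a fit panel of 3 samples yields at most 2
#'   nontrivial components).
#' @return list of class `pca_projection`: `scores` (fit individuals x
#'   PCs), `projected` (projected individuals x PCs), `sdev`, `loadings`,
#'   `center`, `scale_vec`, `n_pc`.
#' @export
pca_fit_project <- function(panel, fit_ids = NULL, project_ids = NULL,
                            scale = c("none", "unit-variance"),
                            n_pc = NULL) {
  scale <- match.arg(scale)
  if (is.null(fit_ids)) {
    fit_ids <- panel$individuals$id[panel$individuals$class == "modern"]
  }
  if (length(fit_ids) < 2) stop("fit panel needs >= 2 individuals",
                                call. = FALSE)
  if (is.null(project_ids)) {
    project_ids <- setdiff(panel$individuals$id, fit_ids)
  }
  fi <- ind_index(panel, fit_ids)
  dosage <- panel$genotypes * (2L / panel$individuals$ploidy)
  X <- dosage[fi, , drop = FALSE]
  center <- colMeans(X, na.rm = TRUE)
  center[is.nan(center)] <- 0
  poly <- apply(X, 2, function(col) {
    v <- col[!is.na(col)]
    length(v) > 0 && any(v != v[1])
  })
  if (!any(poly)) stop("fit panel has zero polymorphic SNPs", call. = FALSE)
  scale_vec <- rep(1, ncol(X))
  if (scale == "unit-variance") {
    p <- center / 2
    scale_vec <- ifelse(poly & p > 0 & p < 1, 1 / sqrt(p * (1 - p)), 1)
  }
  Xc <- sweep(X, 2, center)
  Xc[is.na(Xc)] <- 0                     # mean imputation
  Xc <- sweep(Xc, 2, scale_vec, `*`)
  Xc <- Xc[, poly, drop = FALSE]
  sv <- svd(Xc)
  rank_bound <- min(nrow(Xc) - 1L, ncol(Xc))
  if (is.null(n_pc)) n_pc <- min(10L, rank_bound)
  n_pc <- min(n_pc, rank_bound)
  d <- sv$d[seq_len(n_pc)]
  scores <- sv$u[, seq_len(n_pc), drop = FALSE] %*% diag(d, n_pc)
  rownames(scores) <- fit_ids
  V <- sv$v[, seq_len(n_pc), drop = FALSE]   # loadings over polymorphic SNPs

  proj <- matrix(NA_real_, length(project_ids), n_pc,
                 dimnames = list(project_ids, NULL))
  if (length(project_ids)) {
    pi_ <- ind_index(panel, project_ids)
    poly_idx <- which(poly)
    for (r in seq_along(pi_)) {
      x <- dosage[pi_[r], poly_idx]
      obs <- !is.na(x)
      if (!any(obs)) next
      xc <- (x[obs] - center[poly_idx][obs]) * scale_vec[poly_idx][obs]
      Vs <- V[obs, , drop = FALSE]
      proj[r, ] <- qr.coef(qr(Vs), xc)
    }
  }
  structure(list(scores = scores, projected = proj, sdev = d,
                 loadings = V, center = center, scale_vec = scale_vec,
                 n_pc = n_pc, poly = poly),
            class = "pca_projection")
}
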