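## Binomial-likelihood admixture model: unsupervised EM fit on modern
## individuals, fixed-P projection of (ancient) samples, cluster
## alignment, and RMSE accuracy evaluation over SNP subsets.
##
## Model: individual i with c_i gene copies (ploidy) and derived dosage
## g_im at SNP m has per-copy derived probability f_im = sum_k q_ik p_km.
## log L = sum_im [ g_im log f_im + (c_i - g_im) log(1 - f_im) ]
## (binomial coefficients omitted throughout; they do not affect the
## optimum).  Updates are the classic FRAPPE EM; missing genotypes simply
## drop out of the sums.

EPS_P <- 1e-9

admix_loglik <- function(G, C, Q, P) {
  obs <- !is.na(G)
  g <- ifelse(obs, G, 0)
  cg <- ifelse(obs, C - G, 0)     # C (length n) recycles down columns
  f <- pmin(pmax(Q %*% P, EPS_P), 1 - EPS_P)
  sum(g * log(f) + cg * log1p(-f))
}

run_em <- function(G, C, Q, P, tol, max_iter, update_p = TRUE) {
  obs <- !is.na(G)
  g <- ifelse(obs, G, 0)
  cg <- ifelse(obs, C - G, 0)     # C (length n) recycles down columns
  fit <- .admix_em_cpp(g, cg, Q, P, tol, max_iter, update_p)
  if (fit$decreased) {
    tr <- fit$trace
    stop(sprintf("EM log-likelihood decreased (%.10g -> %.10g)",
                 tr[length(tr) - 1], tr[length(tr)]), call. = FALSE)
  }
  fit
}

#' Fit an admixture model to modern individuals
#'
#' Unsupervised alternating EM for the binomial admixture likelihood with
#' K ancestral clusters.  Each replicate starts from random
#' `Q ~ Dirichlet(1)` rows and `P ~ Uniform(0.05, 0.95)`; the replicate
#' with the greatest final log-likelihood is returned (default 10
#' replicates).  Convergence: relative log-likelihood change below
#' `tol`.  The log-likelihood trace is non-decreasing by construction
#' (EM); a decrease beyond floating-point slack is a hard error.
#'
#' @param panel a [genotype_panel()]; only individuals of class
#'   `"modern"` enter the fit.
#' @param k number of ancestral clusters (1 <= k <= N).
#' @param replicates random restarts (default 10).
#' @param tol relative log-likelihood tolerance (default 1e-7).
#' @param max_iter iteration cap per replicate (default 3000).
#' @param seed RNG seed.
#' @return object of class `admixture_model`: `Q` (N x K, rows on the
#'   simplex), `P` (K x M cluster derived-allele frequencies), `loglik`,
#'   `trace`, `k`, `ids`, `snp_ids`, `replicate` (index of the winning
#'   restart), `replicate_logliks`.
#' @export
fit_admixture <- function(panel, k, replicates = 10, tol = 1e-7,
                          max_iter = 3000, seed = 1) {
  modern <- panel$individuals$class == "modern"
  G <- panel$genotypes[modern, , drop = FALSE]
  storage.mode(G) <- "double"
  C <- panel$individuals$ploidy[modern]
  n <- nrow(G)
  if (k < 1 || k > n) stop("k must be in 1..N", call. = FALSE)
  best <- NULL
  rep_ll <- numeric(replicates)
  for (r in seq_len(replicates)) {
    set.seed(derive_seed(seed, paste0("admix:", k, ":", r)))
    Q0 <- matrix(rexp(n * k), n, k)   # Dirichlet(1) rows
    Q0 <- Q0 / rowSums(Q0)
    P0 <- matrix(runif(k * ncol(G), 0.05, 0.95), k, ncol(G))
    if (k == 1) Q0 <- matrix(1, n, 1)
    fit <- run_em(G, C, Q0, P0, tol, max_iter, update_p = TRUE)
    rep_ll[r] <- fit$loglik
    if (is.null(best) || fit$loglik > best$loglik) {
      best <- fit
      best$replicate <- r
    }
  }
  structure(list(Q = best$Q, P = best$P, loglik = best$loglik,
                 trace = best$trace, k = k,
                 ids = panel$individuals$id[modern],
                 snp_ids = panel$snps$id,
                 iterations = best$iterations, converged = best$converged,
                 replicate = best$replicate, replicate_logliks = rep_ll,
                 seed = seed),
            class = "admixture_model")
}

#' @export
print.admixture_model <- function(x, ...) {
  cat(sprintf(
    "<admixture_model> K = %d, %d individuals x %d SNPs, logL = %.2f\n",
    x$k, nrow(x$Q), ncol(x$P), x$loglik))
  invisible(x)
}

#' Project one individual onto fixed cluster allele frequencies
#'
#' EM over the membership vector q only, with the cluster frequency
#' matrix P held fixed and the likelihood restricted to the individual's
#' non-missing SNPs -- so the projected sample never influences the
#' clustering solution.  Initialization is the uniform simplex point,
#' making the projection deterministic.
#'
#' @param genotypes derived-allele dosage vector over P's SNP list
#'   (NA = missing).
#' @param ploidy 1 or 2.
#' @param P K x M cluster frequency matrix (or an `admixture_model`).
#' @param tol,max_iter convergence controls (as in [fit_admixture()]).
#' @return list of class `projection_result`: `q`, `loglik`, `trace`,
#'   `iterations`, `converged`, `n_sites`.
#' @export
project_individual <- function(genotypes, ploidy, P, tol = 1e-7,
                               max_iter = 3000) {
  if (inherits(P, "admixture_model")) P <- P$P
  use <- !is.na(genotypes)
  if (!any(use)) stop("no overlapping non-missing SNPs", call. = FALSE)
  G <- matrix(as.numeric(genotypes[use]), 1)
  Pm <- P[, use, drop = FALSE]
  k <- nrow(P)
  Q0 <- matrix(1 / k, 1, k)
  fit <- run_em(G, ploidy, Q0, Pm, tol, max_iter, update_p = FALSE)
  structure(list(q = fit$Q[1, ], loglik = fit$loglik, trace = fit$trace,
                 iterations = fit$iterations, converged = fit$converged,
                 n_sites = sum(use)),
            class = "projection_result")
}

#' Align cluster labels between two membership matrices
#'
#' Mixture models are invariant to cluster permutation; before comparing
#' two Q matrices the columns must be matched.  Greedy
#' maximum-correlation matching (the default) pairs the most correlated
#' columns first; `method = "exhaustive"` scans all permutations (exact,
#' fine for the K <= 8 regime this model targets).
#'
#' @param q_ref reference N x K matrix.
#' @param q N x K matrix to relabel.
#' @param method `"greedy"` or `"exhaustive"`.
#' @return the permutation `perm` such that `q[, perm]` aligns with
#'   `q_ref`.
#' @export
align_clusters <- function(q_ref, q, method = c("greedy", "exhaustive")) {
  method <- match.arg(method)
  k <- ncol(q_ref)
  if (k == 1) return(1L)
  score <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(-sum((a - b)^2))
    stats::cor(a, b)
  }
  s <- outer(seq_len(k), seq_len(k),
             Vectorize(function(i, j) score(q_ref[, i], q[, j])))
  if (method == "exhaustive") {
    perms <- perm_matrix(k)
    tot <- apply(perms, 1, function(p) sum(s[cbind(seq_len(k), p)]))
    return(unname(perms[which.max(tot), ]))
  }
  perm <- integer(k)
  free_i <- seq_len(k); free_j <- seq_len(k)
  while (length(free_i)) {
    sub <- s[free_i, free_j, drop = FALSE]
    w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    perm[free_i[w[1]]] <- free_j[w[2]]
    free_i <- free_i[-w[1]]; free_j <- free_j[-w[2]]
  }
  perm
}

perm_matrix <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    left <- sub[, seq_len(pos - 1L), drop = FALSE]
    right <- if (pos <= k - 1L) sub[, pos:(k - 1L), drop = FALSE]
             else sub[, 0, drop = FALSE]
    m <- cbind(left, k, right)
    storage.mode(m) <- "integer"
    m
  }))
}

#' RMSE of membership proportions across SNP subsets
#'
#' Accuracy evaluation of the projection machinery under the missingness
#' of each ancient sample: every modern individual is re-projected onto
#' the fitted cluster frequencies restricted to each SNP subset, columns
#' are aligned to the full-data run, and the root-mean-square error over
#' (individual, cluster) pairs is reported per population.  The baseline
#' is the projection on the full SNP set, so the full subset gives RMSE 0
#' exactly.
#'
#' @param panel the [genotype_panel()] the models were fitted to.
#' @param models list of `admixture_model` objects (one per K).
#' @param subsets named list of SNP index/logical vectors (e.g. the
#'   non-missing mask of each ancient sample).
#' @param tol,max_iter projection convergence controls.
#' @return data.frame with columns `pop`, `k`, `subset`, `n_snps`,
#'   `rmse`.
#' @export
rmse_subset_eval <- function(panel, models, subsets, tol = 1e-7,
                             max_iter = 3000) {
  if (inherits(models, "admixture_model")) models <- list(models)
  modern <- which(panel$individuals$class == "modern")
  pops <- panel$individuals$pop[modern]
  out <- list()
  for (model in models) {
    full_q <- project_all(panel, modern, model$P, seq_len(n_snp(panel)),
                          tol, max_iter)
    for (sname in names(subsets)) {
      sub <- subsets[[sname]]
      idx <- if (is.logical(sub)) which(sub) else as.integer(sub)
      if (!length(idx)) stop("empty SNP subset: ", sname, call. = FALSE)
      sub_q <- project_all(panel, modern, model$P, idx, tol, max_iter)
      perm <- align_clusters(full_q, sub_q)
      sub_q <- sub_q[, perm, drop = FALSE]
      for (pp in unique(pops)) {
        rows <- pops == pp
        rmse <- sqrt(mean((sub_q[rows, , drop = FALSE] -
                           full_q[rows, , drop = FALSE])^2))
        out[[length(out) + 1L]] <- data.frame(
          pop = pp, k = model$k, subset = sname, n_snps = length(idx),
          rmse = rmse, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

project_all <- function(panel, ind_rows, P, snp_idx, tol, max_iter) {
  t(vapply(ind_rows, function(i) {
    g <- rep(NA_integer_, ncol(P))
    g[snp_idx] <- panel$genotypes[i, snp_idx]
    project_individual(g, panel$individuals$ploidy[i], P, tol, max_iter)$q
  }, numeric(nrow(P))))
}
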