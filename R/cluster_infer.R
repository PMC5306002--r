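# Bayesian admixture clustering (Gibbs sampler), Evanno delta-K model
# selection, replicate label alignment, and discriminant analysis of
# principal components (DAPC) with BIC cluster search and a-scores.

# genotype matrix -> per-locus allele-index coding for the sampler
genotypes_to_indices <- function(g) {
  L <- length(g$loci)
  n <- nrow(g$a1)
  X <- matrix(0L, n, 2L * L)
  J <- integer(L)
  allele_maps <- vector("list", L)
  for (l in seq_len(L)) {
    alleles <- sort(unique(c(g$a1[, l], g$a2[, l])))
    alleles <- alleles[!is.na(alleles)]
    J[l] <- length(alleles)
    allele_maps[[l]] <- alleles
    X[, 2 * l - 1] <- ifelse(is.na(g$a1[, l]), 0L,
                             match(g$a1[, l], alleles))
    X[, 2 * l] <- ifelse(is.na(g$a2[, l]), 0L, match(g$a2[, l], alleles))
  }
  list(X = X, J = J, allele_maps = allele_maps)
}

#' Bayesian admixture clustering by Gibbs sampling
#'
#' STRUCTURE-type admixture model with independent Dirichlet(lambda)
#' allele frequencies: each allele copy has a latent cluster of origin,
#' individuals have Dirichlet(alpha) mixed-ancestry vectors Q, and alpha
#' receives a Metropolis random-walk update under a Uniform(0,
#' `alpha_max`) prior. With `locprior`, sampling location informs the
#' prior on Q through per-location mean memberships. The model
#' log-likelihood `lnP_D` is estimated as the posterior mean data
#' log-likelihood minus half its posterior variance.
#'
#' @param g An [ep_genotypes()].
#' @param K Number of clusters (>= 1).
#' @param iters Total Gibbs sweeps (default 2000).
#' @param burnin Burn-in sweeps (default `iters %/% 2`).
#' @param locprior Use the sampling-location prior (needs `site` in the
#'   metadata).
#' @param seed Integer seed (runs are bit-reproducible under a fixed
#'   seed).
#' @param lambda Dirichlet parameter for allele frequencies (1).
#' @param alpha_init,alpha_max,alpha_prop Admixture-parameter initial
#'   value, prior upper bound, and Metropolis proposal SD as a fraction
#'   of the current value.
#' @return A list of class `cluster_run`: `K`, `Q` (posterior mean
#'   membership, rows sum to 1), `P` (per-locus cluster allele
#'   frequencies), `lnP_D`, `loglik` trace, `alpha` trace, `seed`.
#' @export
admixture_gibbs <- function(g, K, iters = 2000L, burnin = iters %/% 2L,
                            locprior = FALSE, seed = 1L, lambda = 1,
                            alpha_init = 1, alpha_max = 10,
                            alpha_prop = 0.025) {
  stopifnot(inherits(g, "ep_genotypes"))
  n <- nrow(g$a1)
  if (K > n) stop_islandpop("K exceeds the number of individuals",
                            "domain_error")
  if (iters <= burnin) stop_islandpop("iters must exceed burnin",
                                      "domain_error")
  enc <- genotypes_to_indices(g)
  loc <- as.integer(factor(g$meta$site)) - 1L
  set.seed(seed)
  res <- .gibbs_admixture_cpp(enc$X, enc$J, as.integer(K),
                              as.integer(iters), as.integer(burnin),
                              lambda, alpha_init, alpha_max, alpha_prop,
                              loc, isTRUE(locprior))
  post <- res$loglik[(burnin + 1):iters]
  lnP_D <- mean(post) - var(post) / 2
  a_post <- res$alpha[(burnin + 1):iters]
  if (K > 1 && !locprior && length(a_post) > 10 &&
      sd(a_post) > 2 * mean(a_post))
    warning("alpha trace variance is large: possible non-convergence")
  rownames(res$Q) <- g$meta$id
  structure(list(K = K, Q = res$Q, P = res$P, lnP_D = lnP_D,
                 loglik = res$loglik, alpha = res$alpha, seed = seed,
                 locprior = locprior),
            class = "cluster_run")
}

#' @export
print.cluster_run <- function(x, ...) {
  cat("<cluster_run> K=", x$K, " lnP_D=", round(x$lnP_D, 2), "\n", sep = "")
  invisible(x)
}

#' Evanno delta-K from replicate clustering runs
#'
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / SD(L(K))`,
#' defined for interior K of a consecutive range with >= 2 replicates.
#'
#' @param runs List of `cluster_run` objects (or a data frame with
#'   columns `K` and `lnP_D`) covering >= 3 consecutive K values.
#' @return A list of class `deltaK_result`: `table` (per-K mean/SD of
#'   lnP_D and deltaK), `best_K` (argmax deltaK), `best_K_likelihood`
#'   (argmax mean lnP_D).
#' @export
select_K <- function(runs) {
  df <- if (is.data.frame(runs)) runs else
    data.frame(K = vapply(runs, `[[`, numeric(1), "K"),
               lnP_D = vapply(runs, `[[`, numeric(1), "lnP_D"))
  agg <- aggregate(lnP_D ~ K, df, function(v) c(mean = mean(v), sd = sd(v),
                                                n = length(v)))
  tab <- data.frame(K = agg$K, mean = agg$lnP_D[, "mean"],
                    sd = agg$lnP_D[, "sd"], n_rep = agg$lnP_D[, "n"])
  tab <- tab[order(tab$K), ]
  if (nrow(tab) < 3 || any(diff(tab$K) != 1))
    stop_islandpop("need >= 3 consecutive K values", "domain_error")
  if (any(tab$n_rep < 2))
    stop_islandpop("need >= 2 replicates per K", "domain_error")
  dK <- rep(NA_real_, nrow(tab))
  for (i in 2:(nrow(tab) - 1)) {
    if (tab$sd[i] == 0) { dK[i] <- NaN; next }  # flagged: zero SD
    dK[i] <- abs(tab$mean[i + 1] - 2 * tab$mean[i] + tab$mean[i - 1]) /
      tab$sd[i]
  }
  tab$deltaK <- dK
  interior <- which(!is.na(dK) & is.finite(dK))
  structure(list(table = tab,
                 best_K = if (length(interior))
                   tab$K[interior[which.max(dK[interior])]] else NA,
                 best_K_likelihood = tab$K[which.max(tab$mean)]),
            class = "deltaK_result")
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1))
    for (pos in seq_len(k))
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  out
}

#' Align replicate membership matrices
#'
#' Permutes the columns of each replicate Q matrix to maximize agreement
#' with the first replicate (Frobenius-norm similarity
#' `G = 1 - ||Q1 - Q P|| / sqrt(2n)`), exhaustively over the K!
#' permutations for K <= 7 and greedily otherwise, and returns the
#' aligned matrices with their consensus mean.
#'
#' @param Qs List of n x K membership matrices (equal shapes).
#' @return A list: `aligned` (list of matrices), `consensus` (mean
#'   matrix, rows sum to 1), `permutations`, `similarity` to the
#'   reference.
#' @export
align_replicates <- function(Qs) {
  if (length(Qs) == 0) stop_islandpop("no replicates", "domain_error")
  dims <- vapply(Qs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_islandpop("replicates have inconsistent shapes", "domain_error")
  K <- ncol(Qs[[1]]); n <- nrow(Qs[[1]])
  ref <- Qs[[1]]
  gsim <- function(A, B) 1 - norm(A - B, "F") / sqrt(2 * n)
  perms <- if (K <= 7) all_permutations(K) else NULL
  aligned <- vector("list", length(Qs))
  permutations <- vector("list", length(Qs))
  sims <- numeric(length(Qs))
  for (r in seq_along(Qs)) {
    Q <- Qs[[r]]
    if (r == 1) {
      best_p <- seq_len(K)
    } else if (!is.null(perms)) {
      scores <- vapply(perms, function(p) gsim(ref, Q[, p, drop = FALSE]),
                       numeric(1))
      best_p <- perms[[which.max(scores)]]
    } else {
      # greedy: repeatedly match the most-correlated column pair
      best_p <- integer(K)
      cost <- crossprod(ref, Q)     # K x K agreement
      free_r <- seq_len(K); free_c <- seq_len(K)
      while (length(free_r)) {
        sub <- cost[free_r, free_c, drop = FALSE]
        ij <- arrayInd(which.max(sub), dim(sub))
        best_p[free_r[ij[1]]] <- free_c[ij[2]]
        free_r <- free_r[-ij[1]]; free_c <- free_c[-ij[2]]
      }
    }
    aligned[[r]] <- Q[, best_p, drop = FALSE]
    permutations[[r]] <- best_p
    sims[r] <- gsim(ref, aligned[[r]])
  }
  consensus <- Reduce(`+`, aligned) / length(aligned)
  list(aligned = aligned, consensus = consensus,
       permutations = permutations, similarity = sims)
}

# LDA that tolerates within-group-constant predictors (perfectly
# separated groups): a deterministic, negligible ripple is added to any
# such column so the pooled within-group covariance is non-singular
robust_lda <- function(x, grp) {
  # collinear predictors are routine for discrete count statistics;
  # lda's warning adds no information here
  tryCatch(suppressWarnings(MASS::lda(x, grouping = grp)),
           error = function(e) {
    eps <- pmax(apply(x, 2, sd), 1) * 1e-5
    ripple <- outer(seq_len(nrow(x)), seq_len(ncol(x)),
                    function(i, j) sin(i * 7.3 + j * 3.1))
    MASS::lda(x + sweep(ripple, 2, eps, "*"), grouping = grp,
              tol = 1e-12)
  })
}

# individuals x alleles count table (0/1/2), missing imputed by
# population mean counts
allele_count_table <- function(g, pops = NULL) {
  popf <- if (is.null(pops)) factor(rep("all", nrow(g$a1))) else
    resolve_pops(g, pops)
  cols <- list()
  for (l in seq_along(g$loci)) {
    alleles <- sort(unique(c(g$a1[, l], g$a2[, l])))
    alleles <- alleles[!is.na(alleles)]
    cnt <- vapply(alleles, function(al)
      (g$a1[, l] == al) + (g$a2[, l] == al), numeric(nrow(g$a1)))
    cnt <- matrix(cnt, nrow = nrow(g$a1))
    miss <- is.na(g$a1[, l])
    if (any(miss)) {
      for (p in levels(popf)) {
        sel <- popf == p
        if (!any(sel & miss)) next
        mu <- colMeans(cnt[sel & !miss, , drop = FALSE])
        if (anyNA(mu)) mu <- colMeans(cnt[!miss, , drop = FALSE])
        cnt[sel & miss, ] <- matrix(mu, sum(sel & miss), length(mu),
                                    byrow = TRUE)
      }
    }
    colnames(cnt) <- paste0(g$loci[l], ".", alleles)
    cols[[l]] <- cnt
  }
  do.call(cbind, cols)
}

#' Discriminant analysis of principal components
#'
#' Centers (unscaled) the individual x allele count table, reduces it by
#' PCA, and runs linear discriminant analysis on the retained PCs.
#'
#' @param g An [ep_genotypes()].
#' @param groups Group assignment (metadata column name or vector), each
#'   group with >= 2 members.
#' @param n_pc Principal components to retain (reduced with a warning if
#'   it exceeds the rank).
#' @param n_da Discriminant axes to keep (default `nlevels - 1`).
#' @return A list of class `dapc_result`: `coords` (individual
#'   coordinates on the DA axes), `assignments`, `groups`,
#'   `reassignment` rate, `n_pc`, `pc_scores`, `loadings`.
#' @export
dapc_fit <- function(g, groups, n_pc, n_da = NULL) {
  grp <- resolve_pops(g, groups)
  if (any(table(grp) < 2)) stop_islandpop("each group needs >= 2 members",
                                          "domain_error")
  if (n_pc < 1) stop_islandpop("n_pc must be >= 1", "domain_error")
  tab <- allele_count_table(g, groups)
  pc <- prcomp(tab, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > 1e-8)
  if (n_pc > rank) {
    warning("n_pc exceeds rank; reduced to ", rank)
    n_pc <- rank
  }
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  n_da <- min(n_da %||% (nlevels(grp) - 1), nlevels(grp) - 1)
  fit <- robust_lda(scores, grp)
  pred <- predict(fit, scores)
  coords <- pred$x[, seq_len(min(n_da, ncol(pred$x))), drop = FALSE]
  structure(list(coords = coords, assignments = pred$class, groups = grp,
                 reassignment = mean(pred$class == grp), n_pc = n_pc,
                 n_da = n_da, pc_scores = scores, lda = fit,
                 pca = pc), class = "dapc_result")
}

#' K-means cluster search with BIC
#'
#' Runs k-means (>= 10 restarts) on retained principal components of
#' the allele count table over a range of k and scores each solution by
#' `BIC(k) = n log(WSS_k / n) + k log(n)` (WSS floored at a small
#' epsilon for degenerate solutions).
#'
#' @param g An [ep_genotypes()].
#' @param k_range Integer vector of cluster counts within `[1, n - 1]`.
#' @param n_pc PCs to retain (default: rank).
#' @param n_start k-means restarts (>= 10).
#' @param seed Seed.
#' @return A list of class `find_clusters_result`: `BIC` (named vector),
#'   `best_k` (minimum BIC), `elbow_k` (maximum second difference),
#'   `assignments` for `best_k`.
#' @export
find_clusters <- function(g, k_range, n_pc = NULL, n_start = 10L,
                          seed = 1L) {
  n <- nrow(g$a1)
  if (any(k_range < 1) || any(k_range > n - 1))
    stop_islandpop("k_range must lie in [1, n-1]", "domain_error")
  tab <- allele_count_table(g)
  pc <- prcomp(tab, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > 1e-8)
  n_pc <- min(n_pc %||% rank, rank)
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  set.seed(seed)
  k_range <- sort(unique(as.integer(k_range)))
  bic <- setNames(numeric(length(k_range)), k_range)
  ass <- vector("list", length(k_range))
  for (ii in seq_along(k_range)) {
    k <- k_range[ii]
    if (k == 1) {
      wss <- sum(scale(scores, scale = FALSE)^2)
      ass[[ii]] <- rep(1L, n)
    } else {
      km <- tryCatch(kmeans(scores, centers = k,
                            nstart = max(10L, n_start), iter.max = 50),
                     error = function(e) NULL)
      if (is.null(km)) {
        # fewer distinct points than centers: cluster by identity
        key <- apply(round(scores, 9), 1, paste, collapse = ",")
        ass[[ii]] <- as.integer(factor(key))
        wss <- 0
      } else {
        wss <- km$tot.withinss
        ass[[ii]] <- km$cluster
      }
    }
    bic[ii] <- n * log(max(wss, 1e-12) / n) + k * log(n)
  }
  elbow <- if (length(bic) >= 3) {
    d2 <- diff(diff(bic))          # positive curvature = elbow
    k_range[which.max(d2) + 1L]
  } else k_range[which.min(bic)]
  structure(list(BIC = bic, best_k = k_range[which.min(bic)],
                 elbow_k = elbow,
                 assignments = ass[[which.min(bic)]]),
            class = "find_clusters_result")
}

#' a-score of a DAPC solution
#'
#' Observed reassignment rate minus the mean reassignment rate when the
#' group labels are permuted (the chance component of discriminant
#' success), per axis-free summary.
#'
#' @param dapc A [dapc_fit()] result.
#' @param n_perm Label permutations (default 20; values < 10 warn).
#' @param seed Seed.
#' @return A list: `a_score`, `observed`, `null_mean`.
#' @export
a_score <- function(dapc, n_perm = 20L, seed = 1L) {
  if (n_perm < 10) warning("n_perm < 10: noisy a-score")
  set.seed(seed)
  obs <- dapc$reassignment
  nullr <- vapply(seq_len(n_perm), function(b) {
    pg <- sample(dapc$groups)
    fit <- robust_lda(dapc$pc_scores, pg)
    mean(predict(fit, dapc$pc_scores)$class == pg)
  }, numeric(1))
  list(a_score = obs - mean(nullr), observed = obs,
       null_mean = mean(nullr))
}

#' Scan retained-PC counts by a-score
#'
#' Fits DAPC for each candidate number of retained PCs and reports the
#' a-score curve and its argmax (the optimum balancing discrimination
#' against overfitting).
#'
#' @param g An [ep_genotypes()].
#' @param groups Group assignment.
#' @param n_pc_grid Candidate PC counts.
#' @param n_perm Permutations per point.
#' @param seed Seed.
#' @return A list: `grid`, `a_scores`, `best_n_pc`.
#' @export
a_score_scan <- function(g, groups, n_pc_grid, n_perm = 20L, seed = 1L) {
  scores <- vapply(seq_along(n_pc_grid), function(ii) {
    fit <- suppressWarnings(dapc_fit(g, groups, n_pc = n_pc_grid[ii]))
    a_score(fit, n_perm = n_perm, seed = seed + ii)$a_score
  }, numeric(1))
  list(grid = n_pc_grid, a_scores = scores,
       best_n_pc = n_pc_grid[which.max(scores)])
}
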