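# Microsatellite diversity, Weir-Cockerham F-statistics, permutation
# tests of differentiation, Queller-Goodnight relatedness, ML inbreeding
# coefficients, HWE permutation tests and least-squares distance trees.

# resolve a population assignment: a metadata column name or a vector
resolve_pops <- function(g, pops) {
  if (is.character(pops) && length(pops) == 1L && pops %in% names(g$meta))
    return(factor(g$meta[[pops]]))
  factor(pops)
}

# per-locus list of (alleles n x 2, pop factor) with complete cases only
locus_data <- function(g, popf) {
  lapply(seq_along(g$loci), function(j) {
    ok <- !is.na(g$a1[, j])
    list(a = cbind(g$a1[ok, j], g$a2[ok, j]), pop = droplevels(popf[ok]),
         pop_full = popf[ok])
  })
}

#' Nei & Chesser diversity statistics
#'
#' Sample-size-corrected estimators of within-population (Hs) and total
#' (Ht) gene diversity (Nei & Chesser 1983), plus observed
#' heterozygosity, per locus and averaged over loci, with jackknife
#' standard errors over populations for the overall values.
#'
#' @param g An [ep_genotypes()].
#' @param pops Population assignment: a metadata column name
#'   (`"site"`/`"region"`) or a vector over individuals.
#' @return A list of class `diversity_result` with per-locus data frame
#'   `per_locus` (`A`, `Ho`, `Hs`, `Ht`) and `overall` (means over loci,
#'   with jackknife SEs).
#' @export
nei_diversity <- function(g, pops) {
  popf <- resolve_pops(g, pops)
  res <- lapply(seq_along(g$loci), function(j) {
    nei_locus(g$a1[, j], g$a2[, j], popf)
  })
  per_locus <- data.frame(locus = g$loci,
                          A = vapply(res, `[[`, numeric(1), "A"),
                          Ho = vapply(res, `[[`, numeric(1), "Ho"),
                          Hs = vapply(res, `[[`, numeric(1), "Hs"),
                          Ht = vapply(res, `[[`, numeric(1), "Ht"))
  # jackknife over populations: drop one pop, recompute mean-over-loci
  lv <- levels(popf)
  jk <- if (length(lv) > 2) {
    vals <- t(vapply(lv, function(p) {
      keep <- popf != p
      r <- lapply(seq_along(g$loci), function(j)
        nei_locus(g$a1[keep, j], g$a2[keep, j], droplevels(popf[keep])))
      c(Ho = mean(vapply(r, `[[`, numeric(1), "Ho"), na.rm = TRUE),
        Hs = mean(vapply(r, `[[`, numeric(1), "Hs"), na.rm = TRUE),
        Ht = mean(vapply(r, `[[`, numeric(1), "Ht"), na.rm = TRUE))
    }, numeric(3)))
    k <- length(lv)
    apply(vals, 2, function(v) sqrt((k - 1) / k * sum((v - mean(v))^2)))
  } else c(Ho = NA, Hs = NA, Ht = NA)
  overall <- data.frame(
    stat = c("Ho", "Hs", "Ht"),
    value = c(mean(per_locus$Ho, na.rm = TRUE),
              mean(per_locus$Hs, na.rm = TRUE),
              mean(per_locus$Ht, na.rm = TRUE)),
    jackknife_se = unname(jk))
  structure(list(per_locus = per_locus, overall = overall),
            class = "diversity_result")
}

nei_locus <- function(a1, a2, popf) {
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]; popf <- droplevels(popf[ok])
  r <- nlevels(popf)
  if (length(a1) == 0 || r == 0)
    return(list(A = 0, Ho = NA, Hs = NA, Ht = NA))
  alleles <- sort(unique(c(a1, a2)))
  A <- length(alleles)
  if (A == 1) return(list(A = 1, Ho = 0, Hs = 0, Ht = 0))
  ns <- as.vector(table(popf))
  ntilde <- 1 / mean(1 / ns)          # harmonic mean sample size
  pmat <- vapply(levels(popf), function(p) {
    sel <- popf == p
    tabulate(match(c(a1[sel], a2[sel]), alleles), length(alleles)) /
      (2 * sum(sel))
  }, numeric(A))
  pmat <- matrix(pmat, nrow = A)
  Ho <- mean(vapply(levels(popf), function(p) {
    sel <- popf == p
    mean(a1[sel] != a2[sel])
  }, numeric(1)))
  Hs <- ntilde / (ntilde - 1) *
    (1 - mean(colSums(pmat^2)) - Ho / (2 * ntilde))
  pbar <- rowMeans(pmat)
  Ht <- 1 - sum(pbar^2) + Hs / (ntilde * r) - Ho / (2 * ntilde * r)
  list(A = A, Ho = Ho, Hs = Hs, Ht = Ht)
}

#' Rarefied allelic richness
#'
#' Expected number of alleles in a standardized subsample of
#' `rarefy_to` gene copies, per population and locus (hypergeometric
#' rarefaction): `Ar = sum_a [1 - C(N - N_a, g) / C(N, g)]`.
#'
#' @param g An [ep_genotypes()].
#' @param pops Population assignment (see [nei_diversity()]).
#' @param rarefy_to Gene copies to rarefy to; default is the smallest
#'   complete gene-copy count over populations and loci. Must be >= 2.
#' @return A matrix (locus x population) of Ar values, with attribute
#'   `rarefy_to`.
#' @export
allelic_richness <- function(g, pops, rarefy_to = NULL) {
  popf <- resolve_pops(g, pops)
  lv <- levels(popf)
  copies <- sapply(seq_along(g$loci), function(j)
    vapply(lv, function(p) 2 * sum(!is.na(g$a1[popf == p, j])), numeric(1)))
  rarefy_to <- rarefy_to %||% min(copies)
  if (rarefy_to < 2)
    stop_islandpop("rarefy_to must be >= 2", "parameter_error")
  out <- matrix(NA_real_, length(g$loci), length(lv),
                dimnames = list(g$loci, lv))
  for (j in seq_along(g$loci)) for (p in lv) {
    sel <- popf == p & !is.na(g$a1[, j])
    all_copies <- c(g$a1[sel, j], g$a2[sel, j])
    N <- length(all_copies)
    if (N < rarefy_to) next
    Na <- table(all_copies)
    out[j, p] <- sum(1 - exp(lchoose(N - Na, rarefy_to) -
                             lchoose(N, rarefy_to)))
  }
  attr(out, "rarefy_to") <- rarefy_to
  out
}

# Weir & Cockerham (1984) variance components for one locus, summed
# over alleles; vectorized over (population x allele) count matrices.
# Core operates on precomputed allele indices so permutation tests can
# reuse the encoding.
wc_components_core <- function(i1, i2, nA, g, r) {
  ns <- tabulate(g, r)
  if (sum(ns > 0) < 2 || nA < 2) return(c(a = 0, b = 0, c = 0))
  nbar <- mean(ns)
  nc <- (r * nbar - sum(ns^2) / (r * nbar)) / (r - 1)
  Cmat <- matrix(tabulate(g + r * (i1 - 1L), r * nA) +
                 tabulate(g + r * (i2 - 1L), r * nA), r, nA)
  het <- i1 != i2
  Hmat <- matrix(tabulate(g[het] + r * (i1[het] - 1L), r * nA) +
                 tabulate(g[het] + r * (i2[het] - 1L), r * nA), r, nA)
  p_i <- Cmat / (2 * ns)
  h_i <- Hmat / ns
  pbar <- colSums(ns * p_i) / (r * nbar)
  s2 <- colSums(ns * (p_i - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(ns * h_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
         (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
         ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = sum(a), b = sum(b), c = sum(cc))
}

wc_locus_components <- function(a1, a2, popf) {
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]; popf <- droplevels(popf[ok])
  r <- nlevels(popf)
  if (r < 2) return(c(a = 0, b = 0, c = 0))
  alleles <- sort(unique(c(a1, a2)))
  nA <- length(alleles)
  if (nA < 2) return(c(a = 0, b = 0, c = 0))
  wc_components_core(match(a1, alleles), match(a2, alleles), nA,
                     as.integer(popf), r)
}

wc_from_components <- function(comp) {
  a <- comp["a"]; b <- comp["b"]; cc <- comp["c"]
  tot <- a + b + cc
  c(FIS = unname(1 - cc / (b + cc)),
    FST = unname(a / tot),
    FIT = unname(1 - cc / tot))
}

#' Weir-Cockerham F-statistics
#'
#' Variance-component estimators f (FIS), theta (FST) and F (FIT) of
#' Weir & Cockerham (1984), per locus and combined over loci (ratios of
#' summed components), with percentile bootstrap-over-loci confidence
#' intervals.
#'
#' @param g An [ep_genotypes()].
#' @param pops Population assignment.
#' @param n_boot Bootstrap replicates over loci (default 1000; a single
#'   locus yields point estimates with CIs flagged unavailable).
#' @param conf Confidence level (default 0.99).
#' @param seed Seed for the bootstrap.
#' @return A list of class `fstats_result`: `per_locus` (raw estimates,
#'   with a companion `per_locus_truncated` where negative values are
#'   shown as zero), `overall`, `ci` and `components`.
#' @export
wc_fstats <- function(g, pops, n_boot = 1000L, conf = 0.99, seed = 1L) {
  popf <- resolve_pops(g, pops)
  if (nlevels(popf) < 2) stop_islandpop("need >= 2 populations",
                                        "domain_error")
  comps <- t(vapply(seq_along(g$loci), function(j)
    wc_locus_components(g$a1[, j], g$a2[, j], popf), numeric(3)))
  rownames(comps) <- g$loci
  per_locus <- t(apply(comps, 1, wc_from_components))
  overall <- wc_from_components(colSums(comps))
  ci <- NULL
  if (length(g$loci) >= 2 && n_boot > 0) {
    set.seed(seed)
    boots <- t(vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(comps), replace = TRUE)
      wc_from_components(colSums(comps[idx, , drop = FALSE]))
    }, numeric(3)))
    alpha <- (1 - conf) / 2
    ci <- apply(boots, 2, quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE)
  }
  trunc <- pmax(per_locus, 0)
  structure(list(per_locus = per_locus, per_locus_truncated = trunc,
                 overall = overall, ci = ci, conf = conf,
                 components = comps),
            class = "fstats_result")
}

# multilocus theta for a subset of individuals (used by permutation test)
multilocus_theta <- function(a1, a2, popf) {
  comp <- c(a = 0, b = 0, c = 0)
  for (j in seq_len(ncol(a1)))
    comp <- comp + wc_locus_components(a1[, j], a2[, j], popf)
  unname(wc_from_components(comp)["FST"])
}

#' Pairwise FST with permutation tests
#'
#' Pairwise multilocus theta between all population pairs; significance
#' by permuting whole multilocus genotypes between the two samples
#' (no HWE assumption), with add-one smoothing, and Bonferroni-adjusted
#' significance flags at `alpha / n_pairs`.
#'
#' @param g An [ep_genotypes()].
#' @param pops Population assignment.
#' @param n_perm Permutations per pair (default 1000; values < 100 log a
#'   warning).
#' @param alpha Nominal significance level before Bonferroni (0.05).
#' @param seed Seed.
#' @return A list of class `pairwise_fst_table`: `fst` and `p` matrices,
#'   `significant` (logical, Bonferroni-adjusted), `bonferroni_alpha`.
#' @export
pairwise_fst_test <- function(g, pops, n_perm = 1000L, alpha = 0.05,
                              seed = 1L) {
  popf <- resolve_pops(g, pops)
  lv <- levels(popf)
  if (length(lv) < 2) stop_islandpop("need >= 2 populations", "domain_error")
  if (n_perm < 100) warning("n_perm < 100: p-values will be coarse")
  npair <- choose(length(lv), 2)
  fst <- p <- matrix(NA_real_, length(lv), length(lv),
                     dimnames = list(lv, lv))
  diag(fst) <- 0
  set.seed(seed)
  for (i in seq_len(length(lv) - 1)) for (j in (i + 1):length(lv)) {
    sel <- popf %in% c(lv[i], lv[j])
    a1 <- g$a1[sel, , drop = FALSE]; a2 <- g$a2[sel, , drop = FALSE]
    gl <- as.integer(droplevels(popf[sel]))
    # precompute per-locus allele encodings once per pair
    enc <- lapply(seq_len(ncol(a1)), function(l) {
      ok <- which(!is.na(a1[, l]))
      alleles <- sort(unique(c(a1[ok, l], a2[ok, l])))
      list(ok = ok, nA = length(alleles),
           i1 = match(a1[ok, l], alleles), i2 = match(a2[ok, l], alleles))
    })
    theta_of <- function(grp) {
      comp <- c(a = 0, b = 0, c = 0)
      for (e in enc)
        if (e$nA >= 2)
          comp <- comp + wc_components_core(e$i1, e$i2, e$nA,
                                            grp[e$ok], 2L)
      unname(wc_from_components(comp)["FST"])
    }
    obs <- theta_of(gl)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      if (theta_of(gl[sample.int(length(gl))]) >= obs)
        exceed <- exceed + 1L
    }
    fst[i, j] <- fst[j, i] <- obs
    p[i, j] <- p[j, i] <- (exceed + 1) / (n_perm + 1)
  }
  structure(list(fst = fst, p = p,
                 significant = p <= alpha / npair,
                 bonferroni_alpha = alpha / npair, n_perm = n_perm),
            class = "pairwise_fst_table")
}

#' Queller-Goodnight relatedness
#'
#' Pairwise relatedness estimator of Queller & Goodnight (1989) with
#' reference allele frequencies computed excluding the focal pair,
#' symmetrized by averaging the two directed values; group means are
#' averages over within-group pairs.
#'
#' @param g An [ep_genotypes()] with at least 3 individuals.
#' @param pops Population assignment (groups for the means).
#' @return A list of class `relatedness_result`: `pairwise` (matrix) and
#'   `group_means`.
#' @export
qg_relatedness <- function(g, pops) {
  popf <- resolve_pops(g, pops)
  n <- nrow(g$a1)
  if (n < 3)
    stop_islandpop("need >= 3 individuals for out-of-pair frequencies",
                   "domain_error")
  L <- length(g$loci)
  r <- matrix(NA_real_, n, n, dimnames = list(g$meta$id, g$meta$id))
  for (i in seq_len(n - 1)) for (jj in (i + 1):n) {
    num_xy <- den_xy <- num_yx <- den_yx <- 0
    any_locus <- FALSE
    for (l in seq_len(L)) {
      ax <- c(g$a1[i, l], g$a2[i, l]); ay <- c(g$a1[jj, l], g$a2[jj, l])
      if (anyNA(ax) || anyNA(ay)) next
      others <- setdiff(seq_len(n), c(i, jj))
      ref <- c(g$a1[others, l], g$a2[others, l])
      ref <- ref[!is.na(ref)]
      if (length(ref) == 0 || length(unique(ref)) < 2) next
      pfun <- function(al) mean(ref == al)
      any_locus <- TRUE
      sim <- function(a, b)  # mean identity of a's alleles to b's
        0.5 * (mean(a[1] == b) + mean(a[2] == b))
      # directed x->y
      px <- vapply(ax, pfun, numeric(1))
      num_xy <- num_xy + (2 * sim(ax, ay) - px[1] - px[2])
      den_xy <- den_xy + (1 + (ax[1] == ax[2]) - px[1] - px[2])
      py <- vapply(ay, pfun, numeric(1))
      num_yx <- num_yx + (2 * sim(ay, ax) - py[1] - py[2])
      den_yx <- den_yx + (1 + (ay[1] == ay[2]) - py[1] - py[2])
    }
    if (!any_locus || den_xy == 0 || den_yx == 0) next
    r[i, jj] <- r[jj, i] <- 0.5 * (num_xy / den_xy + num_yx / den_yx)
  }
  lv <- levels(popf)
  gm <- vapply(lv, function(p) {
    idx <- which(popf == p)
    if (length(idx) < 2) return(NA_real_)
    mean(r[idx, idx][upper.tri(r[idx, idx])], na.rm = TRUE)
  }, numeric(1))
  structure(list(pairwise = r, group_means = gm),
            class = "relatedness_result")
}

#' Maximum-likelihood individual inbreeding coefficients
#'
#' Per individual, maximizes over `F` in [0,1] the product over loci of
#' the genotype probability given population allele frequencies:
#' homozygote aa has probability `F p_a + (1-F) p_a^2`, heterozygote ab
#' `(1-F) 2 p_a p_b`. A coarse grid (step 0.01) is refined with
#' `optimize()` (tolerance 1e-6). Monomorphic loci contribute nothing;
#' individuals with no usable locus are skipped.
#'
#' @param g An [ep_genotypes()].
#' @param pops Population assignment (frequencies come from the
#'   individual's own population).
#' @return A list of class `inbreeding_result`: `F` (per individual) and
#'   `group_stats` (mean, SD per population).
#' @export
inbreeding_mle <- function(g, pops) {
  popf <- resolve_pops(g, pops)
  n <- nrow(g$a1)
  # per pop, per locus allele frequency tables
  freqs <- lapply(levels(popf), function(p) {
    lapply(seq_along(g$loci), function(j) {
      sel <- popf == p & !is.na(g$a1[, j])
      al <- c(g$a1[sel, j], g$a2[sel, j])
      if (length(al) == 0) return(numeric(0))
      tab <- table(al) / length(al)
      setNames(as.numeric(tab), names(tab))
    })
  })
  names(freqs) <- levels(popf)
  Fhat <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    pf <- freqs[[as.character(popf[i])]]
    loglik <- function(F) {
      ll <- 0; used <- FALSE
      for (j in seq_along(g$loci)) {
        a <- g$a1[i, j]; b <- g$a2[i, j]
        if (is.na(a)) next
        p <- pf[[j]]
        if (length(p) < 2) next   # monomorphic: uninformative
        pa <- p[as.character(a)]; pb <- p[as.character(b)]
        if (is.na(pa) || is.na(pb)) next
        pr <- if (a == b) F * pa + (1 - F) * pa^2 else (1 - F) * 2 * pa * pb
        ll <- ll + log(max(pr, 1e-300)); used <- TRUE
      }
      if (!used) return(NA_real_)
      ll
    }
    grid <- seq(0, 1, by = 0.01)
    lg <- vapply(grid, loglik, numeric(1))
    if (all(is.na(lg))) next
    g0 <- grid[which.max(lg)]
    op <- optimize(loglik, c(max(0, g0 - 0.02), min(1, g0 + 0.02)),
                   maximum = TRUE, tol = 1e-6)
    Fhat[i] <- op$maximum
  }
  gs <- do.call(rbind, lapply(levels(popf), function(p) {
    v <- Fhat[popf == p & !is.na(Fhat)]
    data.frame(pop = p, mean = mean(v), sd = sd(v), n = length(v))
  }))
  structure(list(F = setNames(Fhat, g$meta$id), group_stats = gs),
            class = "inbreeding_result")
}

#' Hardy-Weinberg equilibrium permutation test
#'
#' Per locus and population, alleles are shuffled into genotypes and the
#' observed FIS is compared against its permutation distribution
#' (two-tailed, add-one smoothing). Monomorphic loci and populations
#' with fewer than `min_n` individuals are skipped (NA).
#'
#' @param g An [ep_genotypes()].
#' @param pops Population assignment.
#' @param n_perm Permutations (default 1000).
#' @param min_n Minimum individuals (default 5).
#' @param seed Seed.
#' @return Matrix (locus x population) of p-values.
#' @export
hwe_test <- function(g, pops, n_perm = 1000L, min_n = 5L, seed = 1L) {
  popf <- resolve_pops(g, pops)
  lv <- levels(popf)
  out <- matrix(NA_real_, length(g$loci), length(lv),
                dimnames = list(g$loci, lv))
  set.seed(seed)
  fis_stat <- function(a1, a2) {
    al <- c(a1, a2)
    p <- table(al) / length(al)
    he <- 1 - sum(p^2)
    if (he == 0) return(NA_real_)
    ho <- mean(a1 != a2)
    1 - ho / he
  }
  for (j in seq_along(g$loci)) for (p in lv) {
    sel <- popf == p & !is.na(g$a1[, j])
    if (sum(sel) < min_n) next
    a1 <- g$a1[sel, j]; a2 <- g$a2[sel, j]
    obs <- fis_stat(a1, a2)
    if (is.na(obs)) next   # monomorphic
    pool <- c(a1, a2)
    m <- length(a1)
    stat <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      perm <- pool[sample.int(2 * m)]
      stat[b] <- fis_stat(perm[1:m], perm[(m + 1):(2 * m)])
    }
    stat <- stat[!is.na(stat)]
    lo <- (sum(stat <= obs) + 1) / (length(stat) + 1)
    hi <- (sum(stat >= obs) + 1) / (length(stat) + 1)
    out[j, p] <- min(1, 2 * min(lo, hi))
  }
  out
}

#' Neighbor-joining tree with Fitch-Margoliash branch lengths
#'
#' Topology by neighbor joining (Saitou & Nei, via \pkg{ape}), branch
#' lengths re-fitted by non-negative least squares with
#' Fitch-Margoliash weighting `1/d^2`. Negative input distances are
#' clamped to zero with a warning (pairwise FST can be negative).
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @return A list of class `distance_tree`: `tree` (an \pkg{ape}
#'   `phylo`), `newick` string, and the least-squares `fit_ss`.
#' @export
distance_tree <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8) || any(diag(d) != 0))
    stop_islandpop("need a symmetric zero-diagonal distance matrix",
                   "domain_error")
  if (any(d < 0)) {
    warning("negative distances clamped to 0")
    d[d < 0] <- 0
  }
  tr <- ape::nj(as.dist(d))
  n <- nrow(d)
  labs <- rownames(d) %||% paste0("t", seq_len(n))
  # pair x edge incidence for the least-squares fit
  pairs <- combn(n, 2)
  tipidx <- match(labs, tr$tip.label)
  E <- nrow(tr$edge)
  A <- matrix(0, ncol(pairs), E)
  dvec <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- tipidx[pairs[1, k]]; j <- tipidx[pairs[2, k]]
    np <- ape::nodepath(tr, i, j)
    for (s in seq_len(length(np) - 1)) {
      e <- which((tr$edge[, 1] == np[s] & tr$edge[, 2] == np[s + 1]) |
                 (tr$edge[, 2] == np[s] & tr$edge[, 1] == np[s + 1]))
      A[k, e] <- 1
    }
    dvec[k] <- d[pairs[1, k], pairs[2, k]]
  }
  w <- ifelse(dvec > 0, 1 / dvec^2, max(1 / dvec[dvec > 0]^2, 1))
  obj <- function(b) sum(w * (dvec - A %*% b)^2)
  grad <- function(b) -2 * drop(t(A) %*% (w * (dvec - A %*% b)))
  b0 <- pmax(tr$edge.length, 0)
  op <- optim(b0, obj, grad, method = "L-BFGS-B", lower = 0,
              control = list(maxit = 500))
  tr$edge.length <- op$par
  structure(list(tree = tr, newick = ape::write.tree(tr), fit_ss = op$value),
            class = "distance_tree")
}
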