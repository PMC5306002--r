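# Sequence diversity, mismatch-distribution demographic analysis,
# Fu & Li / R2 neutrality tests, T92+G distances and distance-based
# molecular dating for the haploid (mtDNA D-loop) marker.

#' Sequence diversity statistics
#'
#' Computes segregating sites (S), parsimony-informative sites (PI), the
#' minimum number of mutations (eta), singleton mutations (eta_s),
#' per-site nucleotide diversity (pi) and haplotype diversity (Hd).
#' Columns containing any non-ACGT symbol are excluded throughout
#' (complete deletion).
#'
#' @param a An [ep_alignment()] with at least two sequences.
#' @return A list of class `seq_diversity`: `S`, `PI`, `eta`, `eta_s`,
#'   `pi`, `Hd`, `n`, `usable_sites`, and `mean_pairwise` (mean pairwise
#'   differences over usable sites, not per site).
#' @export
seq_diversity <- function(a) {
  stopifnot(inherits(a, "ep_alignment"))
  n <- length(a$ids)
  if (n < 2) stop_islandpop("need at least 2 sequences", "domain_error")
  m <- aln_matrix(a)[, usable_sites(aln_matrix(a)), drop = FALSE]
  L <- ncol(m)
  S <- 0L; PI <- 0L; eta <- 0L; eta_s <- 0L
  for (j in seq_len(L)) {
    tab <- table(m[, j])
    if (length(tab) > 1L) {
      S <- S + 1L
      eta <- eta + length(tab) - 1L
      eta_s <- eta_s + sum(tab == 1L)
      if (sum(tab >= 2L) >= 2L) PI <- PI + 1L
    }
  }
  # mean pairwise differences by brute force over variable columns
  mp <- mean_pairwise_diffs(m)
  pi <- if (L > 0) mp / L else 0
  # haplotype diversity with sample-size correction
  hap <- match(apply(m, 1, paste, collapse = ""),
               unique(apply(m, 1, paste, collapse = "")))
  p <- tabulate(hap) / n
  Hd <- n / (n - 1) * (1 - sum(p^2))
  structure(list(S = S, PI = PI, eta = eta, eta_s = eta_s, pi = pi,
                 Hd = Hd, n = n, usable_sites = L, mean_pairwise = mp),
            class = "seq_diversity")
}

# mean pairwise Hamming distance over the columns of a character matrix
mean_pairwise_diffs <- function(m) {
  n <- nrow(m)
  if (n < 2) return(0)
  tot <- 0
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    if (length(tab) > 1L)
      tot <- tot + (choose(n, 2) - sum(choose(tab, 2)))
  }
  tot / choose(n, 2)
}

# vector of pairwise difference counts for all n(n-1)/2 pairs
pairwise_diff_counts <- function(a) {
  m <- aln_matrix(a)
  m <- m[, usable_sites(m), drop = FALSE]
  n <- nrow(m)
  out <- integer(n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- k + 1L
    out[k] <- sum(m[i, ] != m[j, ])
  }
  out
}

#' Mismatch distribution and sudden-expansion fit
#'
#' The observed distribution of pairwise nucleotide differences is
#' compared with the expectation under a sudden (stepwise) demographic
#' expansion. Harpending's raggedness statistic and the sum of squared
#' deviations from the fitted curve are reported.
#'
#' The sudden-expansion curve is the exact mixture expectation for a
#' population of mutation-scaled size `theta0` that jumped to `theta1`
#' at mutational time `tau` before present: pairwise coalescence times
#' are piecewise exponential and the difference count is Poisson along
#' both lineages. The three parameters are fitted by bounded least
#' squares on the class frequencies, initialized from moment estimators.
#'
#' @param a An [ep_alignment()], n >= 3.
#' @param max_class Optional largest difference class to tabulate
#'   (defaults to the observed maximum).
#' @return A list of class `mismatch_result` with `observed` (frequency
#'   vector over classes `0..d`), `expected` (fitted model curve),
#'   `raggedness_r`, `SSD`, and `fit` (`theta0`, `theta1`, `tau`,
#'   `converged`).
#' @export
mismatch_analysis <- function(a, max_class = NULL) {
  stopifnot(inherits(a, "ep_alignment"))
  if (length(a$ids) < 3) stop_islandpop("need n >= 3", "domain_error")
  d <- pairwise_diff_counts(a)
  dmax <- max_class %||% max(d)
  obs <- tabulate(factor(d, levels = 0:dmax)) / length(d)
  r <- harpending_raggedness(obs)
  if (max(d) == 0L) {
    # all pairs identical: fit skipped; degenerate single-class
    # distribution yields raggedness 1 by the stated convention
    fit <- list(theta0 = 0, theta1 = 0, tau = 0, converged = FALSE,
                degenerate = TRUE)
    return(structure(list(observed = obs, expected = obs,
                          raggedness_r = r, SSD = 0, fit = fit),
                     class = "mismatch_result"))
  }
  fit <- fit_sudden_expansion(obs)
  expd <- expansion_mismatch_curve(fit$tau, fit$theta0, fit$theta1,
                                   length(obs) - 1L)
  structure(list(observed = obs, expected = expd, raggedness_r = r,
                 SSD = sum((obs - expd)^2), fit = fit),
            class = "mismatch_result")
}

# Harpending's raggedness: sum of squared successive differences over
# classes 0..d with an appended zero class
harpending_raggedness <- function(freq) {
  x <- c(freq, 0)
  sum(diff(x)^2)
}

# Expected mismatch class probabilities under sudden expansion.
# Scaled so that, at equilibrium theta, P(i) is geometric with mean
# theta; tau is in units of 1/(2u) (u = per-sequence rate).
expansion_mismatch_curve <- function(tau, theta0, theta1, dmax) {
  i <- 0:dmax
  # P(i) = int_0^tau (2/th1) e^{-2s/th1} Pois(i; 2s) ds
  #      + e^{-2tau/th1} int_0^inf (2/th0) e^{-2s/th0} Pois(i; 2(tau+s)) ds
  # evaluated by Gauss-Legendre quadrature on [0, tau] and a
  # substitution u = s/(1+s) on the tail.
  quad <- function(f, lo, hi, k = 96) {
    if (hi <= lo) return(numeric(dmax + 1))
    x <- lo + (hi - lo) * (0.5 + 0.5 * gl_nodes$x)
    w <- (hi - lo) * 0.5 * gl_nodes$w
    vals <- vapply(seq_along(x), function(ii) f(x[ii]), numeric(dmax + 1))
    drop(vals %*% w)
  }
  p1 <- if (theta1 > 1e-9)
    quad(function(s) (2 / theta1) * exp(-2 * s / theta1) *
           stats::dpois(i, 2 * s), 0, max(tau, 0))
  else numeric(dmax + 1)
  surv <- if (theta1 > 1e-9) exp(-2 * tau / theta1) else as.numeric(tau <= 0)
  p2 <- if (theta0 > 1e-9) {
    quad(function(u) {
      s <- u / (1 - u)
      (2 / theta0) * exp(-2 * s / theta0) * stats::dpois(i, 2 * (tau + s)) /
        (1 - u)^2
    }, 0, 1 - 1e-9)
  } else stats::dpois(i, 2 * tau)   # instantaneous coalescence before tau
  p <- p1 + surv * p2
  p / sum(p)
}

gl_nodes <- local({
  # 96-point Gauss-Legendre nodes/weights on [-1, 1]
  n <- 96
  j <- seq_len(n - 1)
  b <- j / sqrt(4 * j^2 - 1)
  A <- matrix(0, n, n)
  A[cbind(j, j + 1)] <- b
  A[cbind(j + 1, j)] <- b
  e <- eigen(A, symmetric = TRUE)
  list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
})

fit_sudden_expansion <- function(obs) {
  dmax <- length(obs) - 1L
  mean_mm <- sum((0:dmax) * obs)
  # moment initialization: tau ~ mean mismatch, theta0 small
  init <- c(theta0 = max(0.1, mean_mm / 10), theta1 = max(5, 4 * mean_mm),
            tau = max(0.5, mean_mm))
  obj <- function(par) {
    th0 <- par[1]; th1 <- par[2]; tau <- par[3]
    if (th1 < th0) return(1e6 + (th0 - th1)^2)
    e <- expansion_mismatch_curve(tau, th0, th1, dmax)
    sum((obs - e)^2)
  }
  op <- optim(init, obj, method = "L-BFGS-B",
              lower = c(0, 1e-3, 0), upper = c(50, 5000, 50),
              control = list(maxit = 300))
  list(theta0 = unname(op$par[1]), theta1 = unname(op$par[2]),
       tau = unname(op$par[3]), converged = op$convergence == 0,
       degenerate = FALSE)
}

# ---- Fu & Li D*, F* and Ramos-Onsins & Rozas R2 -------------------------

# Direct statistics from (n, eta, eta_s, mean pairwise diffs k, S,
# per-sequence singleton loads U). Variance constants follow the
# corrected forms of Simonsen, Churchill & Aquadro (1995).
fu_li_dstar <- function(n, eta, eta_s) {
  an <- harmonic(n - 1); bn <- harmonic2(n - 1); an1 <- an + 1 / n
  cn <- if (n > 2) 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2)) else 1
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  uD <- (n / (n - 1)) * (an - n / (n - 1)) - vD
  num <- (n / (n - 1)) * eta - an * eta_s
  num / sqrt(uD * eta + vD * eta^2)
}

fu_li_fstar <- function(n, eta, eta_s, k) {
  an <- harmonic(n - 1); bn <- harmonic2(n - 1); an1 <- an + 1 / n
  cn <- if (n > 2) 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2)) else 1
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (2 / (n - 1)) * (4 * bn - 6 + 8 / n)) / (an^2 + bn)
  uF <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           2 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / an - vF
  num <- k - ((n - 1) / n) * eta_s
  num / sqrt(uF * eta + vF * eta^2)
}

r2_stat <- function(n, U, k, S) {
  if (S == 0) return(NA_real_)
  sqrt(mean((U - k / 2)^2)) / S
}

# summary quantities needed by the neutrality statistics
neutrality_summaries <- function(a) {
  m <- aln_matrix(a)
  m <- m[, usable_sites(m), drop = FALSE]
  n <- nrow(m)
  eta <- 0L; eta_s <- 0L; S <- 0L
  U <- integer(n)
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    if (length(tab) > 1L) {
      S <- S + 1L
      eta <- eta + length(tab) - 1L
      singles <- names(tab)[tab == 1L]
      eta_s <- eta_s + length(singles)
      for (s in singles) U[which(m[, j] == s)] <- U[which(m[, j] == s)] + 1L
    }
  }
  list(n = n, S = S, eta = eta, eta_s = eta_s,
       k = mean_pairwise_diffs(m), U = U)
}

#' Fu & Li's D* and F* and the R2 neutrality tests
#'
#' Statistics are computed without an outgroup (starred versions), with
#' R2 following Ramos-Onsins & Rozas. P-values come from coalescent
#' simulation under the standard neutral model conditional on the sample
#' size and Watterson's theta estimated from the data: two-tailed
#' (equal-tail doubling) for D* and F*, lower-tail for R2.
#'
#' @param a An [ep_alignment()] with at least one segregating site.
#' @param reps Number of neutral coalescent replicates (default 10000).
#' @param seed Integer seed for the null simulation.
#' @return A list of class `neutrality_stats` with `D_star`, `F_star`,
#'   `R2`, matching `p_*` values, `reps` and `theta_w`.
#' @export
neutrality_tests <- function(a, reps = 10000L, seed = 1L) {
  stopifnot(inherits(a, "ep_alignment"))
  ns <- neutrality_summaries(a)
  if (ns$S == 0)
    stop_islandpop("no segregating sites: statistics undefined",
                   "undefined_statistic_error")
  D <- fu_li_dstar(ns$n, ns$eta, ns$eta_s)
  F_ <- fu_li_fstar(ns$n, ns$eta, ns$eta_s, ns$k)
  R2 <- r2_stat(ns$n, ns$U, ns$k, ns$S)
  theta_w <- ns$S / harmonic(ns$n - 1)
  null <- neutral_null_distribution(ns$n, theta_w, reps, seed)
  two_tail <- function(obs, sim) {
    sim <- sim[is.finite(sim)]
    lo <- mean(sim <= obs); hi <- mean(sim >= obs)
    min(1, 2 * min(lo, hi))
  }
  p_D <- two_tail(D, null$D)
  p_F <- two_tail(F_, null$F)
  p_R2 <- mean(null$R2[is.finite(null$R2)] <= R2)
  structure(list(D_star = D, F_star = F_, R2 = R2,
                 p_D_star = p_D, p_F_star = p_F, p_R2 = p_R2,
                 reps = reps, theta_w = theta_w),
            class = "neutrality_stats")
}

# Null distribution of (D*, F*, R2) under the standard neutral
# coalescent with fixed theta (mutations Poisson on the genealogy).
# Works directly on mutation carrier counts; no sequences are built.
neutral_null_distribution <- function(n, theta, reps, seed = 1L) {
  set.seed(seed)
  D <- F_ <- R2 <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- sim_neutral_site_frequencies(n, theta)
    if (sim$S == 0) { D[r] <- F_[r] <- R2[r] <- NA_real_; next }
    D[r] <- fu_li_dstar(n, sim$eta, sim$eta_s)
    F_[r] <- fu_li_fstar(n, sim$eta, sim$eta_s, sim$k)
    R2[r] <- r2_stat(n, sim$U, sim$k, sim$S)
  }
  list(D = D, F = F_, R2 = R2)
}

# one neutral replicate: coalescent topology as leaf-sets, mutations
# Poisson(theta/2 * branch length in coalescent units)
sim_neutral_site_frequencies <- function(n, theta) {
  # branch lengths: while k lineages, each of k branches gains
  # Exp(k(k-1)/2) / k ... we track per-lineage leaf sets and per-lineage
  # accumulated length, then drop mutations proportionally.
  sets <- as.list(seq_len(n))
  lens <- numeric(n)
  seg_sets <- vector("list", 2 * n)  # branches (leaf-set, length)
  seg_len <- numeric(2 * n)
  nseg <- 0L
  k <- n
  while (k > 1) {
    t_k <- rexp(1, k * (k - 1) / 2)
    lens <- lens + t_k
    pick <- sample.int(k, 2)
    i <- min(pick); j <- max(pick)
    # close the two merging branches
    nseg <- nseg + 1L; seg_sets[[nseg]] <- sets[[i]]; seg_len[nseg] <- lens[i]
    nseg <- nseg + 1L; seg_sets[[nseg]] <- sets[[j]]; seg_len[nseg] <- lens[j]
    sets[[i]] <- c(sets[[i]], sets[[j]])
    lens[i] <- 0
    sets[[j]] <- NULL
    lens <- lens[-j]
    k <- k - 1L
  }
  seg_sets <- seg_sets[seq_len(nseg)]
  seg_len <- seg_len[seq_len(nseg)]
  tot <- sum(seg_len)
  M <- rpois(1, theta / 2 * tot)
  U <- integer(n)
  if (M == 0)
    return(list(S = 0L, eta = 0L, eta_s = 0L, k = 0, U = U))
  br <- sample.int(nseg, M, replace = TRUE, prob = seg_len)
  counts <- lengths(seg_sets)[br]
  eta_s <- 0L
  pairs <- 0
  for (mi in seq_len(M)) {
    c_m <- counts[mi]
    pairs <- pairs + c_m * (n - c_m)
    if (c_m == 1L) {
      eta_s <- eta_s + 1L
      U[seg_sets[[br[mi]]][1]] <- U[seg_sets[[br[mi]]][1]] + 1L
    } else if (c_m == n - 1L) {
      eta_s <- eta_s + 1L
      out_leaf <- setdiff(seq_len(n), seg_sets[[br[mi]]])
      U[out_leaf] <- U[out_leaf] + 1L
    }
  }
  # infinite-sites: each mutation its own site
  list(S = M, eta = M, eta_s = eta_s, k = pairs / (n * (n - 1) / 2), U = U)
}

# ---- substitution model distances and dating ---------------------------

#' Substitution model descriptor
#'
#' @param name `"T92G"` (Tamura 3-parameter with gamma rates) or `"HKY"`.
#' @param gamma_shape Gamma shape for among-site rate variation
#'   (`Inf` = uniform rates).
#' @param prop_invariant Proportion of invariant sites (HKY simulation).
#' @param kappa Transition/transversion rate ratio (HKY).
#' @param gc_content GC content for T92 (`NULL` = estimate from data).
#' @return A list of class `subst_model`.
#' @export
subst_model <- function(name = c("T92G", "HKY"), gamma_shape = 0.3,
                        prop_invariant = 0, kappa = 2, gc_content = NULL) {
  name <- match.arg(name)
  stopifnot(gamma_shape > 0, prop_invariant >= 0, prop_invariant < 1)
  structure(list(name = name, gamma_shape = gamma_shape,
                 prop_invariant = prop_invariant, kappa = kappa,
                 gc_content = gc_content), class = "subst_model")
}

is_transition <- function(x, y) {
  (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "T") | (x == "T" & y == "C")
}

#' Tamura three-parameter distance with gamma rate heterogeneity
#'
#' Closed-form T92 distance from the transition proportion P, the
#' transversion proportion Q and the GC content, with the logarithmic
#' terms replaced by their gamma-corrected counterparts
#' `a * (u^(-1/a) - 1)`. GC content defaults to the mean of the two
#' sequences being compared. Sites with non-ACGT symbols in either
#' sequence are excluded pairwise.
#'
#' @param x,y Equal-length sequences (character strings).
#' @param m A [subst_model()] (T92G); `gamma_shape = Inf` gives the
#'   uncorrected T92 distance.
#' @return Substitutions per site (numeric scalar).
#' @export
ml_distance <- function(x, y, m = subst_model("T92G", gamma_shape = 0.3)) {
  x <- strsplit(toupper(x), "")[[1]]
  y <- strsplit(toupper(y), "")[[1]]
  if (length(x) != length(y))
    stop_islandpop("sequences differ in length", "domain_error")
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  x <- x[ok]; y <- y[ok]
  L <- length(x)
  if (L == 0) stop_islandpop("no usable sites", "domain_error")
  diff <- x != y
  P <- sum(diff & is_transition(x, y)) / L
  Q <- sum(diff & !is_transition(x, y)) / L
  gc <- m$gc_content %||% mean(c(x, y) %in% c("G", "C"))
  h <- 2 * gc * (1 - gc)
  w1 <- 1 - P / h - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop_islandpop("distance formula argument <= 0 (saturation)",
                   "saturation_error")
  a <- m$gamma_shape
  corr <- function(u) if (is.finite(a)) a * (u^(-1 / a) - 1) else -log(u)
  h * corr(w1) + 0.5 * (1 - h) * corr(w2)
}

#' Calibrate a substitution rate from a dated divergence
#'
#' `rate = D_ML / (2 * T_cal)`: half the per-site divergence accrues on
#' each branch per million years.
#'
#' @param D_ML Substitutions per site between the two lineages.
#' @param T_cal Calibration age in My (> 0).
#' @return Rate in substitutions/site/My.
#' @export
calibrate_rate <- function(D_ML, T_cal) {
  if (D_ML < 0 || T_cal <= 0)
    stop_islandpop("need D_ML >= 0 and T_cal > 0", "domain_error")
  D_ML / (2 * T_cal)
}

#' Date a divergence from distance and rate
#'
#' `T = D_ML / (2 r)`, with the inputs carried along for audit.
#'
#' @param D_ML Substitutions per site.
#' @param rate_r Rate in substitutions/site/My (> 0).
#' @return A list of class `dating_result` with `D_ML`, `rate_r` and `T`
#'   (My).
#' @export
date_divergence <- function(D_ML, rate_r) {
  if (rate_r <= 0 || D_ML < 0)
    stop_islandpop("need rate_r > 0 and D_ML >= 0", "domain_error")
  structure(list(D_ML = D_ML, rate_r = rate_r, T = D_ML / (2 * rate_r)),
            class = "dating_result")
}
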