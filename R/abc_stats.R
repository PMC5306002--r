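# Summary statistics for ABC: single-population and pairwise statistics
# for sequence (mtDNA) and microsatellite datasets, in a fixed registry
# order. Degenerate statistics (e.g. Tajima's D with S = 0) are imputed
# as 0 and flagged.

# internal sequence dataset: integer state matrix (n x segregating-site
# candidates), total length L, population labels
seq_dataset <- function(states, L, pop) {
  structure(list(type = "seq", states = states, L = L,
                 pop = as.character(pop)), class = "abc_dataset")
}

msat_dataset <- function(loci, pop, motif = NULL, range_units = 40L) {
  structure(list(type = "msat", loci = loci, pop = as.character(pop),
                 motif = motif, range_units = range_units),
            class = "abc_dataset")
}

#' Convert an alignment to an ABC sequence dataset
#'
#' @param a An [ep_alignment()] with labels (population per sequence).
#' @param pop Optional population vector overriding the labels.
#' @return An internal `abc_dataset` usable by [summary_stats()].
#' @export
as_abc_dataset <- function(a, pop = NULL) {
  stopifnot(inherits(a, "ep_alignment"))
  pop <- pop %||% a$labels
  if (is.null(pop)) stop_islandpop("no population labels", "domain_error")
  m <- aln_matrix(a)
  m <- m[, usable_sites(m), drop = FALSE]
  var <- which(apply(m, 2, function(cl) length(unique(cl)) > 1))
  states <- matrix(match(m[, var, drop = FALSE], c("A", "C", "G", "T")),
                   nrow = nrow(m))
  seq_dataset(states, ncol(m), as.character(pop))
}

# ---- per-group sequence statistics -------------------------------------

# per-state column counts (4 x sites)
state_counts <- function(st) {
  vapply(1:4, function(s) colSums(st == s), numeric(ncol(st)))
}

# counts-based within-group quantities from a state matrix
seq_group_quants <- function(st) {
  n <- nrow(st)
  if (n < 2 || ncol(st) == 0)
    return(list(S = 0L, k = 0, nhap = 1L, Hd = 0))
  tab <- matrix(state_counts(st), ncol = 4)
  S <- sum(rowSums(tab > 0) > 1)
  sum_pairs <- sum(choose(n, 2) - rowSums(choose(tab, 2)))
  key <- apply(st, 1, paste, collapse = ",")
  p <- table(key) / n
  list(S = S, k = sum_pairs / choose(n, 2), nhap = length(p),
       Hd = n / (n - 1) * (1 - sum(p^2)))
}

# mean pairwise differences only (hot path for permutation tests)
seq_k_within <- function(st) {
  n <- nrow(st)
  if (n < 2 || ncol(st) == 0) return(0)
  tab <- matrix(state_counts(st), ncol = 4)
  sum(choose(n, 2) - rowSums(choose(tab, 2))) / choose(n, 2)
}

tajima_d <- function(n, S, k) {
  if (S == 0 || n < 4) return(0)  # degenerate -> 0
  a1 <- harmonic(n - 1); a2 <- harmonic2(n - 1)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

seq_between_quants <- function(st1, st2) {
  n1 <- nrow(st1); n2 <- nrow(st2)
  if (ncol(st1) == 0) return(0)
  t1 <- matrix(state_counts(st1), ncol = 4)
  t2 <- matrix(state_counts(st2), ncol = 4)
  sum(n1 * n2 - rowSums(t1 * t2)) / (n1 * n2)
}

# ---- microsatellite helpers --------------------------------------------

msat_group_quants <- function(sizes, motif, range_units) {
  # sizes: vector of gene copies
  n <- length(sizes)
  tab <- table(sizes)
  p <- tab / n
  A <- length(tab)
  Hs <- if (n > 1) n / (n - 1) * (1 - sum(p^2)) else 0
  V <- if (n > 1) var(sizes) else 0
  M <- A / (diff(range(sizes)) / motif + 1)
  list(A = A, Hs = Hs, V = V, M = M)
}

#' Summary statistics of a dataset
#'
#' For sequence data, per population and pooled: haplotype count,
#' segregating sites, per-site nucleotide diversity, haplotype
#' diversity, Tajima's D, and private segregating sites; per pair:
#' Hudson's FST (1 - Hw/Hb) and mean between-population diversity. For
#' microsatellites, per population: mean allele count, mean unbiased
#' expected heterozygosity, mean allele-size variance, mean M-ratio;
#' per pair: Weir-Cockerham theta, the (delta mu)^2 distance and
#' allele-sharing distance. Names follow a fixed registry order;
#' degenerate values are imputed 0.
#'
#' @param dataset An `abc_dataset` ([as_abc_dataset()] or simulated).
#' @return Named numeric vector.
#' @export
summary_stats <- function(dataset) {
  stopifnot(inherits(dataset, "abc_dataset"))
  pops <- sort(unique(dataset$pop))
  if (dataset$type == "seq") seq_summary_stats(dataset, pops)
  else msat_summary_stats(dataset, pops)
}

seq_summary_stats <- function(ds, pops) {
  st <- ds$states; L <- ds$L
  out <- c()
  grp_idx <- lapply(pops, function(p) which(ds$pop == p))
  q_all <- seq_group_quants(st)
  n_all <- nrow(st)
  out <- c(out, pool_nhap = q_all$nhap, pool_S = q_all$S,
           pool_pi = q_all$k / L, pool_Hd = q_all$Hd,
           pool_tajD = tajima_d(n_all, q_all$S, q_all$k))
  for (ii in seq_along(pops)) {
    idx <- grp_idx[[ii]]
    sti <- st[idx, , drop = FALSE]
    q <- seq_group_quants(sti)
    # private segregating sites: variable within pop, invariant outside
    priv <- 0L
    if (ncol(st) > 0 && length(idx) > 1) {
      oth <- st[-idx, , drop = FALSE]
      for (j in seq_len(ncol(st))) {
        vin <- length(unique(sti[, j])) > 1
        vout <- nrow(oth) == 0 || length(unique(oth[, j])) == 1
        if (vin && vout) priv <- priv + 1L
      }
    }
    v <- c(q$nhap, q$S, q$k / L, q$Hd, tajima_d(length(idx), q$S, q$k),
           priv)
    names(v) <- paste0(pops[ii], "_", c("nhap", "S", "pi", "Hd", "tajD",
                                        "privS"))
    out <- c(out, v)
  }
  if (length(pops) > 1) {
    for (i in seq_len(length(pops) - 1)) for (j in (i + 1):length(pops)) {
      st1 <- st[grp_idx[[i]], , drop = FALSE]
      st2 <- st[grp_idx[[j]], , drop = FALSE]
      kb <- seq_between_quants(st1, st2)
      kw <- 0.5 * (seq_group_quants(st1)$k + seq_group_quants(st2)$k)
      fst <- if (kb > 0) 1 - kw / kb else 0
      v <- c(fst, kb / L)
      names(v) <- paste0("pair_", pops[i], "_", pops[j], "_",
                         c("fst", "pib"))
      out <- c(out, v)
    }
  }
  out
}

msat_summary_stats <- function(ds, pops) {
  out <- c()
  nl <- length(ds$loci)
  motif <- ds$motif %||% rep(2L, nl)
  for (p in pops) {
    A <- Hs <- V <- M <- numeric(nl)
    for (l in seq_len(nl)) {
      sz <- ds$loci[[l]][ds$pop == p, , drop = FALSE]
      q <- msat_group_quants(as.vector(sz), motif[l], ds$range_units)
      A[l] <- q$A; Hs[l] <- q$Hs; V[l] <- q$V; M[l] <- q$M
    }
    v <- c(mean(A), mean(Hs), mean(V), mean(M))
    names(v) <- paste0(p, "_", c("meanA", "meanHs", "sizevar", "Mratio"))
    out <- c(out, v)
  }
  if (length(pops) > 1) {
    for (i in seq_len(length(pops) - 1)) for (j in (i + 1):length(pops)) {
      p1 <- pops[i]; p2 <- pops[j]
      comp <- c(a = 0, b = 0, c = 0)
      dmu2 <- das <- numeric(nl)
      popf <- factor(ds$pop[ds$pop %in% c(p1, p2)])
      for (l in seq_len(nl)) {
        sz <- ds$loci[[l]]
        sel <- ds$pop %in% c(p1, p2)
        comp <- comp + wc_locus_components(sz[sel, 1], sz[sel, 2], popf)
        m1 <- as.vector(sz[ds$pop == p1, , drop = FALSE])
        m2 <- as.vector(sz[ds$pop == p2, , drop = FALSE])
        dmu2[l] <- ((mean(m1) - mean(m2)) / motif[l])^2
        als <- sort(unique(c(m1, m2)))
        f1 <- tabulate(match(m1, als), length(als)) / length(m1)
        f2 <- tabulate(match(m2, als), length(als)) / length(m2)
        das[l] <- 1 - sum(pmin(f1, f2))
      }
      theta <- wc_from_components(comp)["FST"]
      if (!is.finite(theta)) theta <- 0
      v <- c(unname(theta), mean(dmu2), mean(das))
      names(v) <- paste0("pair_", p1, "_", p2, "_",
                         c("fst", "dmu2", "das"))
      out <- c(out, v)
    }
  }
  out
}
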