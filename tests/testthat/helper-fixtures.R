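# Fixture builders and independent oracles used across the suite.

make_genotypes <- function(site, a1, a2, region = site,
                           loci = paste0("L", seq_len(ncol(a1)))) {
  n <- length(site)
  meta <- data.frame(id = sprintf("i%03d", seq_len(n)), site = site,
                     region = region, sex = "unknown", stage = "adult",
                     stringsAsFactors = FALSE)
  colnames(a1) <- colnames(a2) <- loci
  ep_genotypes(meta, a1, a2, loci)
}

# two populations fixed for alternative alleles at `L` loci
fixed_diff_genotypes <- function(n_per = 10L, L = 10L) {
  site <- rep(c("A", "B"), each = n_per)
  a1 <- matrix(0L, 2 * n_per, L)
  for (l in seq_len(L)) a1[, l] <- ifelse(site == "A", 100L + 4L * l,
                                          102L + 4L * l)
  make_genotypes(site, a1, a1)
}

# one population drawn in Hardy-Weinberg proportions
hwe_genotypes <- function(n = 30L, L = 8L, n_alleles = 5L, seed = 1L,
                          site = "P1") {
  set.seed(seed)
  a1 <- a2 <- matrix(0L, n, L)
  for (l in seq_len(L)) {
    p <- as.vector(rgamma(n_alleles, 1)); p <- p / sum(p)
    a1[, l] <- 100L + 2L * sample.int(n_alleles, n, TRUE, prob = p)
    a2[, l] <- 100L + 2L * sample.int(n_alleles, n, TRUE, prob = p)
  }
  make_genotypes(rep(site, n), a1, a2)
}

# ---- independent oracles ------------------------------------------------

# Weir & Cockerham (1984) variance components, transcribed independently
# from the published single-allele formulas
oracle_wc_components <- function(a1, a2, pop) {
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]; pop <- factor(pop[ok])
  r <- nlevels(pop)
  ns <- tapply(a1, pop, length)
  nbar <- mean(ns)
  nc <- (r * nbar - sum(ns^2) / (r * nbar)) / (r - 1)
  alleles <- unique(c(a1, a2))
  out <- c(a = 0, b = 0, c = 0)
  for (al in alleles) {
    p_i <- h_i <- numeric(r)
    for (i in seq_len(r)) {
      x1 <- a1[pop == levels(pop)[i]]; x2 <- a2[pop == levels(pop)[i]]
      p_i[i] <- mean(c(x1 == al, x2 == al))
      h_i[i] <- mean((x1 == al) + (x2 == al) == 1)
    }
    pbar <- sum(ns * p_i) / sum(ns)
    s2 <- sum(ns * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ns * h_i) / sum(ns)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    out <- out + c(a = a, b = b, c = hbar / 2)
  }
  out
}

# Fu & Li / R2 statistics recomputed directly from an alignment's
# character matrix (independent of the package's bookkeeping)
oracle_neutrality <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(m)
  eta <- 0; eta_s <- 0; S <- 0
  U <- numeric(n)
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    if (length(tab) < 2) next
    S <- S + 1
    eta <- eta + length(tab) - 1
    for (st in names(tab)[tab == 1]) {
      eta_s <- eta_s + 1
      U[m[, j] == st] <- U[m[, j] == st] + 1
    }
  }
  k <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    k <- k + sum(m[i, ] != m[j, ])
  k <- k / choose(n, 2)
  an <- sum(1 / seq_len(n - 1)); bn <- sum(1 / seq_len(n - 1)^2)
  an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    2 / (n - 1) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * n * an * (an + 1) / (n - 1)^2) / (an^2 + bn)
  uD <- n / (n - 1) * (an - n / (n - 1)) - vD
  Dstar <- (n / (n - 1) * eta - an * eta_s) / sqrt(uD * eta + vD * eta^2)
  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           2 / (n - 1) * (4 * bn - 6 + 8 / n)) / (an^2 + bn)
  uF <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           2 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / an - vF
  Fstar <- (k - (n - 1) / n * eta_s) / sqrt(uF * eta + vF * eta^2)
  R2 <- sqrt(mean((U - k / 2)^2)) / S
  list(D_star = Dstar, F_star = Fstar, R2 = R2, S = S, eta = eta,
       eta_s = eta_s, k = k)
}

# brute-force per-site nucleotide diversity over all pairs
oracle_pi <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  ok <- apply(m, 2, function(cl) all(cl %in% c("A", "C", "G", "T")))
  m <- m[, ok, drop = FALSE]
  n <- nrow(m)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) tot <- tot + sum(m[i, ] != m[j, ])
  tot / choose(n, 2) / ncol(m)
}

# small deterministic alignment fixture (n = 5, S = 3)
toy_alignment <- function() {
  ep_alignment(paste0("s", 1:5),
               c("ACGTACGTAA",
                 "ACGTACGTAA",
                 "ACGTACGTTA",
                 "ACCTACGTAA",
                 "GCGTACGTAA"))
}
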