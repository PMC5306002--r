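test_that("Nei-Chesser diversity matches direct computation", {
  # one pop, all AB heterozygotes (n = 4)
  g <- make_genotypes(rep("A", 4), matrix(100L, 4), matrix(104L, 4))
  d <- nei_diversity(g, "site")
  expect_equal(d$per_locus$Ho, 1)
  ntilde <- 4
  hs_direct <- ntilde / (ntilde - 1) * (1 - 0.5 - 1 / (2 * ntilde))
  expect_equal(d$per_locus$Hs, hs_direct)

  # two pops fixed for different alleles
  g2 <- fixed_diff_genotypes(n_per = 8, L = 1)
  d2 <- nei_diversity(g2, "site")
  expect_equal(d2$per_locus$Ho, 0)
  expect_equal(d2$per_locus$Hs, 0)
  expect_equal(d2$per_locus$Ht, 0.5)

  # monomorphic locus
  g3 <- make_genotypes(rep(c("A", "B"), each = 4), matrix(100L, 8),
                       matrix(100L, 8))
  d3 <- nei_diversity(g3, "site")
  expect_equal(unlist(d3$per_locus[, c("Ho", "Hs", "Ht")]),
               c(Ho = 0, Hs = 0, Ht = 0))
})

test_that("pooling two identical populations leaves Ht close to Hs", {
  g0 <- hwe_genotypes(n = 25, L = 4, seed = 3)
  g <- make_genotypes(rep(c("A", "B"), each = 25),
                      rbind(g0$a1, g0$a1), rbind(g0$a2, g0$a2))
  d <- nei_diversity(g, "site")
  expect_lt(max(abs(d$per_locus$Ht - d$per_locus$Hs)), 0.02)
})

test_that("rarefied allelic richness follows the hypergeometric form", {
  # allele copies {A:3, B:1}, N = 4, rarefied to 2 -> 1.5
  g <- make_genotypes(rep("A", 2), matrix(c(100L, 100L), 2),
                      matrix(c(100L, 104L), 2))
  ar <- allelic_richness(g, "site", rarefy_to = 2)
  expect_equal(unname(ar[1, 1]), 1.5)
  # rarefying to N gives the observed count
  ar4 <- allelic_richness(g, "site", rarefy_to = 4)
  expect_equal(unname(ar4[1, 1]), 2)
  # single allele: 1 at any depth
  g2 <- make_genotypes(rep("A", 3), matrix(100L, 3), matrix(100L, 3))
  expect_equal(unname(allelic_richness(g2, "site", rarefy_to = 2)[1, 1]), 1)
  expect_error(allelic_richness(g, "site", rarefy_to = 1),
               class = "parameter_error")
})

test_that("Weir-Cockerham components match the independent oracle", {
  set.seed(7)
  # 2-pop, 2-locus toy with unbalanced sizes and missing data
  site <- rep(c("A", "B"), c(6, 9))
  a1 <- matrix(sample(c(100L, 102L, 104L), 30, TRUE), 15)
  a2 <- matrix(sample(c(100L, 102L, 104L), 30, TRUE), 15)
  a1[3, 1] <- NA; a2[3, 1] <- NA
  g <- make_genotypes(site, a1, a2)
  fs <- wc_fstats(g, "site", n_boot = 0)
  for (l in 1:2) {
    orc <- oracle_wc_components(g$a1[, l], g$a2[, l], site)
    expect_equal(unname(fs$components[l, ]), unname(orc),
                 tolerance = 1e-12)
  }
  # combined estimators are ratios of summed components
  tot <- colSums(fs$components)
  expect_equal(unname(fs$overall["FST"]), unname(tot["a"] / sum(tot)))
  expect_equal(unname(fs$overall["FIS"]),
               unname(1 - tot["c"] / (tot["b"] + tot["c"])))
  expect_equal(unname(fs$overall["FIT"]), unname(1 - tot["c"] / sum(tot)))

  # complete differentiation
  gfd <- fixed_diff_genotypes(10, 4)
  expect_equal(unname(wc_fstats(gfd, "site", n_boot = 0)$overall["FST"]), 1)
})

test_that("theta is near zero in one panmictic population split in two", {
  g0 <- hwe_genotypes(n = 120, L = 8, seed = 9)
  g <- make_genotypes(rep(c("A", "B"), 60), g0$a1, g0$a2)
  fs <- wc_fstats(g, "site", n_boot = 100, seed = 2)
  expect_lt(abs(fs$overall["FST"]), 0.02)
})

test_that("theta tracks the island-model expectation 1/(1+4Nm)", {
  # Balding-Nichols frequencies with F = 1/(1+4Nm)
  set.seed(13)
  for (Fst in c(0.05, 0.2)) {
    npop <- 8; n <- 40; L <- 10
    a1 <- a2 <- matrix(0L, npop * n, L)
    for (l in seq_len(L)) {
      p <- runif(1, 0.2, 0.8)
      for (i in seq_len(npop)) {
        pi_ <- rbeta(1, p * (1 - Fst) / Fst, (1 - p) * (1 - Fst) / Fst)
        rows <- (i - 1) * n + seq_len(n)
        a1[rows, l] <- 100L + 2L * rbinom(n, 1, pi_)
        a2[rows, l] <- 100L + 2L * rbinom(n, 1, pi_)
      }
    }
    g <- make_genotypes(rep(paste0("P", 1:npop), each = n), a1, a2)
    fs <- wc_fstats(g, "site", n_boot = 200, seed = 4)
    expect_true(fs$ci[1, "FST"] <= Fst * 1.35 &&
                  fs$ci[2, "FST"] >= Fst * 0.65)
  }
})

test_that("pairwise FST permutation test behaves at both extremes", {
  # fixed difference: minimal attainable p
  gfd <- fixed_diff_genotypes(8, 4)
  pw <- pairwise_fst_test(gfd, "site", n_perm = 199, seed = 1)
  expect_equal(pw$p["A", "B"], 1 / 200)
  expect_true(pw$significant["A", "B"])
  expect_equal(diag(pw$fst), c(A = 0, B = 0))

  # identical duplicated halves: not significant
  g0 <- hwe_genotypes(n = 40, L = 6, seed = 5)
  g <- make_genotypes(rep(c("A", "B"), 20), g0$a1, g0$a2)
  pw2 <- pairwise_fst_test(g, "site", n_perm = 199, seed = 1)
  expect_gt(pw2$p["A", "B"], 0.05)

  # seeded reproducibility
  pw3 <- pairwise_fst_test(g, "site", n_perm = 199, seed = 1)
  expect_identical(pw2$p, pw3$p)
  expect_warning(pairwise_fst_test(gfd, "site", n_perm = 50, seed = 1),
                 "coarse")
})

test_that("Queller-Goodnight relatedness behaves for twins and strangers", {
  set.seed(31)
  # identical multilocus genotypes at 10 polymorphic loci -> r near 1
  n <- 12; L <- 10
  a1 <- matrix(100L + 2L * sample.int(6, n * L, TRUE), n)
  a2 <- matrix(100L + 2L * sample.int(6, n * L, TRUE), n)
  a1[2, ] <- a1[1, ]; a2[2, ] <- a2[1, ]   # twin pair
  g <- make_genotypes(rep("A", n), a1, a2)
  r <- qg_relatedness(g, "site")
  expect_gt(r$pairwise[1, 2], 0.9)

  # unrelated simulated pairs: mean near 0
  g2 <- hwe_genotypes(n = 60, L = 8, n_alleles = 6, seed = 17)
  r2 <- qg_relatedness(g2, "site")
  vals <- r2$pairwise[upper.tri(r2$pairwise)]
  expect_gt(length(vals[!is.na(vals)]), 500)
  expect_lt(abs(mean(vals, na.rm = TRUE)), 0.05)
  expect_equal(unname(r2$group_means["P1"]), mean(vals, na.rm = TRUE))

  # two individuals: no out-of-pair reference frequencies
  g3 <- make_genotypes(rep("A", 2), matrix(c(100L, 102L), 2),
                       matrix(c(104L, 106L), 2))
  expect_error(qg_relatedness(g3, "site"), class = "domain_error")
})

test_that("inbreeding MLE matches a 1-D optimizer oracle", {
  # fully heterozygous individual -> F = 0
  set.seed(41)
  n <- 20; L <- 6
  a1 <- matrix(100L + 2L * sample.int(4, n * L, TRUE), n)
  a2 <- matrix(100L + 2L * sample.int(4, n * L, TRUE), n)
  het <- a1[1, ] == a2[1, ]
  a2[1, het] <- a1[1, het] + 2L
  g <- make_genotypes(rep("A", n), a1, a2)
  res <- inbreeding_mle(g, "site")
  expect_lt(res$F[1], 0.02)

  # homozygote for rare alleles -> high F
  n2 <- 20
  b1 <- b2 <- matrix(0L, n2, 4)
  for (l in 1:4) {
    al <- c(rep(100L, 2), rep(102L, 2 * n2 - 2))  # freq(100) ~ 0.05
    b1[, l] <- al[seq(1, 2 * n2, 2)]
    b2[, l] <- al[seq(2, 2 * n2, 2)]
  }
  # individual 1 is homozygous 100/100 at every locus
  g2 <- make_genotypes(rep("A", n2), b1, b2)
  res2 <- inbreeding_mle(g2, "site")
  expect_gt(res2$F[1], 0.9)

  # oracle: direct optimize() on the same likelihood for a 2-locus toy
  g3 <- make_genotypes(rep("A", 10),
                       cbind(c(100L, rep(c(100L, 102L), c(4, 5))),
                             c(104L, rep(c(104L, 106L), c(6, 3)))),
                       cbind(c(100L, rep(c(102L, 102L), c(4, 5))),
                             c(104L, rep(c(106L, 106L), c(6, 3)))))
  res3 <- inbreeding_mle(g3, "site")
  pfun <- function(l, al) {
    x <- c(g3$a1[, l], g3$a2[, l]); mean(x == al)
  }
  ll <- function(F) {
    tot <- 0
    for (l in 1:2) {
      a <- g3$a1[1, l]; b <- g3$a2[1, l]
      pa <- pfun(l, a); pb <- pfun(l, b)
      tot <- tot + log(if (a == b) F * pa + (1 - F) * pa^2 else
        (1 - F) * 2 * pa * pb)
    }
    tot
  }
  orc <- optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-9)$maximum
  expect_equal(unname(res3$F[1]), orc, tolerance = 1e-3)
})

test_that("HWE permutation test calibrates and detects extremes", {
  # all-homozygote two-allele pop, n = 20
  a1 <- matrix(rep(c(100L, 102L), 10), 20)
  g <- make_genotypes(rep("A", 20), a1, a1)
  p <- hwe_test(g, "site", n_perm = 499, seed = 1)
  expect_lte(p[1, 1], 0.01)

  # monomorphic locus skipped
  g2 <- make_genotypes(rep("A", 10), matrix(100L, 10), matrix(100L, 10))
  expect_true(is.na(hwe_test(g2, "site")[1, 1]))

  # type-I error near nominal under HWE
  set.seed(6)
  rej <- 0; nsim <- 400
  for (s in seq_len(nsim)) {
    gs <- hwe_genotypes(n = 25, L = 1, n_alleles = 4, seed = 1000 + s)
    ps <- hwe_test(gs, "site", n_perm = 199, seed = s)
    if (!is.na(ps[1, 1]) && ps[1, 1] <= 0.05) rej <- rej + 1
  }
  expect_gt(rej / nsim, 0.015)
  expect_lt(rej / nsim, 0.09)
})

test_that("distance trees recover additive matrices exactly", {
  # 3 taxa: closed-form star branch lengths
  d <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d["a", "b"] <- d["b", "a"] <- 0.3
  d["a", "c"] <- d["c", "a"] <- 0.5
  d["b", "c"] <- d["c", "b"] <- 0.6
  tr <- distance_tree(d)
  bl <- setNames(tr$tree$edge.length,
                 tr$tree$tip.label[tr$tree$edge[, 2]])
  expect_equal(bl[["a"]], (0.3 + 0.5 - 0.6) / 2, tolerance = 1e-6)
  expect_equal(bl[["b"]], (0.3 + 0.6 - 0.5) / 2, tolerance = 1e-6)
  expect_equal(bl[["c"]], (0.5 + 0.6 - 0.3) / 2, tolerance = 1e-6)

  # 4-taxon additive matrix: true topology and lengths recovered
  tru <- ape::read.tree(text = "((a:0.1,b:0.2):0.15,c:0.3,d:0.4);")
  dm <- as.matrix(ape::cophenetic.phylo(tru))
  fit <- distance_tree(dm)
  expect_equal(fit$fit_ss, 0, tolerance = 1e-8)
  expect_equal(ape::dist.topo(ape::unroot(tru), fit$tree), 0,
               ignore_attr = TRUE)
  dfit <- as.matrix(ape::cophenetic.phylo(fit$tree))
  expect_equal(dfit[rownames(dm), colnames(dm)], dm, tolerance = 1e-6)

  # negative entries are clamped with a warning
  d2 <- dm; d2["a", "b"] <- d2["b", "a"] <- -0.01
  expect_warning(distance_tree(d2), "clamped")
})
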