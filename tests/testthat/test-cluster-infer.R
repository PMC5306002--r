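test_that("admixture sampler separates fixed populations and reproduces", {
  g <- fixed_diff_genotypes(n_per = 10, L = 10)
  run <- admixture_gibbs(g, K = 2, iters = 600, burnin = 300, seed = 3)
  expect_equal(unname(rowSums(run$Q)), rep(1, 20), tolerance = 1e-9)
  hard <- apply(run$Q, 1, which.max)
  expect_equal(length(unique(hard[1:10])), 1)
  expect_equal(length(unique(hard[11:20])), 1)
  expect_false(hard[1] == hard[20])       # 100% correct split
  expect_gt(mean(apply(run$Q, 1, max)), 0.95)

  run2 <- admixture_gibbs(g, K = 2, iters = 600, burnin = 300, seed = 3)
  expect_identical(run$Q, run2$Q)         # bit-reproducible
  expect_identical(run$loglik, run2$loglik)

  expect_error(admixture_gibbs(g, K = 30), class = "domain_error")
  expect_error(admixture_gibbs(g, K = 2, iters = 100, burnin = 100),
               class = "domain_error")
})

test_that("K = 1 likelihood matches the pooled multinomial oracle", {
  g <- hwe_genotypes(n = 30, L = 6, n_alleles = 4, seed = 23)
  run <- admixture_gibbs(g, K = 1, iters = 800, burnin = 400, seed = 1)
  expect_true(all(run$Q == 1))
  ll <- 0
  for (l in seq_along(g$loci)) {
    al <- c(g$a1[, l], g$a2[, l])
    p <- table(al) / length(al)
    ll <- ll + sum(log(p[as.character(al)]))
  }
  # posterior-mean likelihood sits a little below the pooled MLE value
  expect_lt(abs(run$lnP_D - ll), max(4, 0.1 * abs(ll)))
  expect_lte(run$lnP_D, ll + 1e-6)
})

test_that("fully admixed individuals get intermediate memberships", {
  set.seed(19)
  n_per <- 12; L <- 10
  # parents: two fixed populations; F1s carry one allele from each
  aA <- 100L; aB <- 120L
  site <- c(rep("A", n_per), rep("B", n_per), rep("H", 8))
  a1 <- matrix(0L, length(site), L); a2 <- a1
  for (l in seq_len(L)) {
    a1[site == "A", l] <- aA + 4L * l; a2[site == "A", l] <- aA + 4L * l
    a1[site == "B", l] <- aB + 4L * l; a2[site == "B", l] <- aB + 4L * l
    a1[site == "H", l] <- aA + 4L * l; a2[site == "H", l] <- aB + 4L * l
  }
  g <- make_genotypes(site, a1, a2)
  run <- admixture_gibbs(g, K = 2, iters = 800, burnin = 400, seed = 2)
  qh <- run$Q[site == "H", ]
  expect_true(all(colMeans(qh) > 0.3 & colMeans(qh) < 0.7))
})

test_that("delta-K arithmetic matches the worked example", {
  runs <- data.frame(K = rep(1:4, each = 2),
                     lnP_D = rep(c(-1000, -900, -890, -889), each = 2) +
                       rep(c(-1, 1) * sqrt(2), 4))
  # SD of two points at +/- sqrt(2) is 2
  res <- select_K(runs)
  expect_equal(res$table$sd, rep(2, 4))
  expect_equal(res$table$deltaK[2], 45)
  expect_equal(res$table$deltaK[3], 4.5)
  expect_equal(res$best_K, 2)
  expect_equal(res$best_K_likelihood, 4)

  # linear L(K): second difference vanishes
  lin <- data.frame(K = rep(1:4, each = 2),
                    lnP_D = rep(-100 * (1:4), each = 2) +
                      rep(c(-1, 1), 4))
  expect_equal(select_K(lin)$table$deltaK[2:3], c(0, 0))

  # zero SD flagged
  z <- data.frame(K = rep(1:3, each = 2), lnP_D = rep(c(-3, -2, -1), each = 2))
  expect_true(is.nan(select_K(z)$table$deltaK[2]))

  expect_error(select_K(data.frame(K = c(1, 1, 2, 2),
                                   lnP_D = c(-2, -1, -2, -1))),
               class = "domain_error")
})

test_that("replicate alignment recovers column permutations", {
  set.seed(4)
  Q1 <- matrix(rgamma(60, 1), 20)
  Q1 <- Q1 / rowSums(Q1)
  Q2 <- Q1[, c(3, 1, 2)]
  al <- align_replicates(list(Q1, Q2))
  expect_equal(al$aligned[[2]], Q1, ignore_attr = TRUE)
  expect_equal(al$similarity[2], 1)
  expect_equal(al$permutations[[2]], c(2, 3, 1))

  # exhaustive-search oracle at K = 3
  Q3 <- matrix(rgamma(60, 1), 20); Q3 <- Q3 / rowSums(Q3)
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  scores <- vapply(perms, function(p)
    1 - norm(Q1 - Q3[, p], "F") / sqrt(2 * nrow(Q1)), numeric(1))
  al3 <- align_replicates(list(Q1, Q3))
  expect_equal(al3$similarity[2], max(scores))

  # consensus rows still sum to one
  expect_equal(rowSums(al3$consensus), rep(1, 20), tolerance = 1e-12)

  expect_error(align_replicates(list(Q1, Q1[1:10, ])),
               class = "domain_error")
})

test_that("DAPC separates structured groups and a-scores behave", {
  g <- fixed_diff_genotypes(n_per = 15, L = 8)
  fit <- suppressWarnings(dapc_fit(g, "site", n_pc = 4))
  expect_equal(fit$reassignment, 1)
  expect_equal(ncol(fit$coords), 1)       # K - 1 axes
  a <- a_score(fit, n_perm = 20, seed = 1)
  expect_gt(a$a_score, 0.3)

  # homogeneous data: a-score near zero
  gh <- hwe_genotypes(n = 60, L = 8, seed = 33)
  gh$meta$site <- rep(c("X", "Y", "Z"), 20)
  fit0 <- dapc_fit(gh, "site", n_pc = 2)
  a0 <- a_score(fit0, n_perm = 30, seed = 2)
  expect_lt(abs(a0$a_score), 0.15)

  # n_pc above rank is reduced with a warning
  expect_warning(dapc_fit(g, "site", n_pc = 500), "rank")
})

test_that("BIC cluster search finds the elbow at the true k", {
  set.seed(12)
  # three well-separated clusters
  g <- fixed_diff_genotypes(n_per = 12, L = 8)
  site <- c(rep("A", 12), rep("B", 12), rep("C", 12))
  a1 <- matrix(0L, 36, 8)
  for (l in 1:8) a1[, l] <- c(rep(100L + 4L * l, 12),
                              rep(102L + 4L * l, 12),
                              rep(140L + 4L * l, 12))
  g3 <- make_genotypes(site, a1, a1)
  fc <- find_clusters(g3, 1:6, seed = 2)
  expect_equal(fc$elbow_k, 3)
  expect_equal(length(unique(fc$assignments[1:12])), 1)

  # a single tight cluster: BIC minimized at k = 1
  g1 <- make_genotypes(rep("A", 20), matrix(100L, 20, 4),
                       matrix(100L + 2L, 20, 4))
  fc1 <- find_clusters(g1, 1:4, seed = 3)
  expect_equal(fc1$best_k, 1)

  # k near n is guarded (finite BIC)
  fcn <- find_clusters(g1, c(1, 19), seed = 4)
  expect_true(all(is.finite(fcn$BIC)))

  expect_error(find_clusters(g1, 0:3), class = "domain_error")
})

test_that("a-score scan reports an interior optimum on structured data", {
  g <- generate_hierarchy(n_region = 2, n_subpop = 2, n_per_subpop = 12,
                          n_loci = 6, seed = 7)
  sc <- a_score_scan(g, "site", n_pc_grid = c(2, 5, 10, 20),
                     n_perm = 15, seed = 3)
  expect_length(sc$a_scores, 4)
  expect_true(sc$best_n_pc %in% c(2, 5, 10, 20))
})
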