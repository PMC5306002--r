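test_that("diversity statistics match hand enumeration", {
  a <- ep_alignment(paste0("s", 1:4), c("AAAA", "AATA", "AACA", "GAAA"))
  d <- seq_diversity(a)
  expect_equal(d$S, 2)
  expect_equal(d$PI, 0)
  expect_equal(d$eta, 3)
  expect_equal(d$eta_s, 3)

  ident <- ep_alignment(paste0("s", 1:3), rep("ACGT", 3))
  d2 <- seq_diversity(ident)
  expect_equal(d2$S, 0)
  expect_equal(d2$pi, 0)
  expect_equal(d2$Hd, 0)

  expect_error(seq_diversity(ep_alignment("x", "ACGT")),
               class = "domain_error")
})

test_that("pi equals the brute-force pairwise oracle", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(4:12, 1)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 30, TRUE,
                   prob = c(0.5, 0.3, 0.1, 0.1)), collapse = ""),
      character(1))
    a <- ep_alignment(paste0("s", seq_len(n)), seqs)
    expect_equal(seq_diversity(a)$pi, oracle_pi(seqs), tolerance = 1e-12)
  }
})

test_that("haplotype diversity is label-invariant and 0 iff monomorphic", {
  seqs <- c("AAT", "ATA", "AAT", "TAA", "ATA")
  a <- ep_alignment(paste0("s", 1:5), seqs)
  b <- ep_alignment(paste0("x", 1:5), rev(seqs))
  expect_equal(seq_diversity(a)$Hd, seq_diversity(b)$Hd)
  expect_gt(seq_diversity(a)$Hd, 0)
})

test_that("mismatch distribution, raggedness and expansion fit", {
  ident <- ep_alignment(paste0("s", 1:3), rep("ACGTACGT", 3))
  mm <- mismatch_analysis(ident)
  expect_equal(mm$observed, 1)            # single class at 0 differences
  expect_equal(mm$raggedness_r, 1)        # degenerate convention
  expect_false(mm$fit$converged)

  # pairwise differences {1,1,2,1,2,1} -> classes (0,1,2) = (0, 4/6, 2/6)
  a <- ep_alignment(paste0("s", 1:4), c("AA", "AT", "TA", "TT"))
  mm2 <- mismatch_analysis(a)
  expect_equal(mm2$observed, c(0, 4 / 6, 2 / 6))
  x <- c(mm2$observed, 0)
  expect_equal(mm2$raggedness_r, sum(diff(x)^2))
  expect_true(mm2$fit$theta1 >= mm2$fit$theta0)
  expect_gte(mm2$fit$tau, 0)
  expect_equal(sum(mm2$expected), 1, tolerance = 1e-6)

  expect_error(mismatch_analysis(ep_alignment(c("a", "b"), c("AA", "AT"))),
               class = "domain_error")
})

test_that("expansion curve reduces to the equilibrium geometric at tau=0", {
  th <- 3
  p <- islandpop:::expansion_mismatch_curve(0, th, th, 15)
  geom <- th^(0:15) / (th + 1)^(1:16)
  expect_equal(p, geom / sum(geom), tolerance = 1e-6)
})

test_that("neutrality statistics match an independent formula script", {
  a <- toy_alignment()
  expect_equal(seq_diversity(a)$S, 3)
  nt <- neutrality_tests(a, reps = 200, seed = 5)
  o <- oracle_neutrality(a$seqs)
  expect_equal(nt$D_star, o$D_star, tolerance = 1e-12)
  expect_equal(nt$F_star, o$F_star, tolerance = 1e-12)
  expect_equal(nt$R2, o$R2, tolerance = 1e-12)
  expect_true(all(c(nt$p_D_star, nt$p_F_star, nt$p_R2) >= 0 &
                    c(nt$p_D_star, nt$p_F_star, nt$p_R2) <= 1))

  mono <- ep_alignment(paste0("s", 1:5), rep("ACGT", 5))
  expect_error(neutrality_tests(mono),
               class = "undefined_statistic_error")
})

test_that("T92+G distance matches its closed form and properties", {
  s <- strrep("ACGT", 25)
  m <- subst_model("T92G", gamma_shape = 0.3)
  expect_equal(ml_distance(s, s, m), 0)

  # 100 bp, 10 transitions (A->G), 0 transversions, GC = 0.5
  x <- paste(rep("A", 100), collapse = "")
  y <- paste(c(rep("G", 10), rep("A", 90)), collapse = "")
  P <- 0.1; a <- 0.3
  m2 <- subst_model("T92G", gamma_shape = 0.3, gc_content = 0.5)
  h2 <- 2 * 0.5 * 0.5
  expect_equal(ml_distance(x, y, m2),
               h2 * a * ((1 - P / h2)^(-1 / a) - 1), tolerance = 1e-12)
  # GC estimated from the sequences themselves (balanced pair)
  x3 <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")
  y3 <- paste(c(rep(c("A", "C", "G", "T"), 20),
                rep(c("G", "C", "A", "T"), 5)), collapse = "")
  gc3 <- 0.5; h3 <- 2 * gc3 * (1 - gc3)
  P3 <- mean(strsplit(x3, "")[[1]] != strsplit(y3, "")[[1]])
  expect_equal(ml_distance(x3, y3, m),
               h3 * a * ((1 - P3 / h3)^(-1 / a) - 1), tolerance = 1e-12)

  # symmetric, exceeds p-distance, and -> T92 as shape -> Inf
  set.seed(2)
  xv <- sample(c("A", "C", "G", "T"), 200, TRUE)
  yv <- xv
  flip <- sample(200, 20)
  yv[flip] <- vapply(yv[flip], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  x2 <- paste(xv, collapse = ""); y2 <- paste(yv, collapse = "")
  d12 <- ml_distance(x2, y2, m)
  expect_equal(d12, ml_distance(y2, x2, m), tolerance = 1e-12)
  pdist <- mean(strsplit(x2, "")[[1]] != strsplit(y2, "")[[1]])
  expect_gt(d12, pdist)
  dinf <- ml_distance(x2, y2, subst_model("T92G", gamma_shape = Inf))
  expect_gt(d12, dinf)
  expect_gt(dinf, pdist)

  # saturation
  xs <- strrep("A", 50); ys <- strrep("G", 50)
  expect_error(ml_distance(xs, ys, m), class = "saturation_error")
})

test_that("rate calibration and dating arithmetic", {
  expect_equal(calibrate_rate(0, 12), 0)
  expect_equal(calibrate_rate(0.12, 12), 0.005)
  expect_equal(calibrate_rate(0.016, 1), 0.008)
  expect_error(calibrate_rate(-1, 12), class = "domain_error")

  expect_equal(date_divergence(0, 0.005)$T, 0)
  expect_equal(date_divergence(0.008, 0.004)$T, 1.0)
  expect_equal(date_divergence(0.0184, 0.008)$T, 1.15)
  expect_error(date_divergence(0.1, 0), class = "domain_error")

  # dating with a rate calibrated at T0 recovers T0 for any D
  for (D in c(0.01, 0.05, 0.3)) {
    T0 <- 12
    expect_equal(date_divergence(D, calibrate_rate(D, T0))$T, T0)
  }
})
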