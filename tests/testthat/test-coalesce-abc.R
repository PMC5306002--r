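one_pop <- function(Ne = 1000) scenario("one", "A", list(A = Ne), list())

test_that("genealogy simulation honors structure and events", {
  set.seed(1)
  # single sample: no coalescence
  tr <- simulate_genealogy(one_pop(), c(), c(A = 1))
  expect_equal(tr$n, 1)
  expect_equal(max(tr$time), 0)

  # two pops merged at t = 0 behave as one population
  scen2 <- scenario("m0", c("A", "B"), list(A = 1000, B = 1000),
                    list(event_merge(0, "B", "A")))
  t_merged <- replicate(600, max(simulate_genealogy(
    scen2, c(), c(A = 2, B = 2))$time))
  t_one <- replicate(600, max(simulate_genealogy(
    one_pop(), c(), c(A = 4))$time))
  expect_gt(suppressWarnings(ks.test(t_merged, t_one))$p.value, 0.001)

  # stranded lineages: two pops that never merge
  scen3 <- scenario("bad", c("A", "B"), list(A = 1000, B = 1000), list())
  expect_error(simulate_genealogy(scen3, c(), c(A = 2, B = 2)),
               class = "scenario_validity_error")

  # parameterized times resolve and order correctly
  scen4 <- scenario("p", "A", list(A = "N"),
                    list(event_size("t1", "A", "N2")))
  tr4 <- simulate_genealogy(scen4, c(N = 500, t1 = 100, N2 = 5), c(A = 6))
  expect_equal(tr4$n, 6)
  expect_error(simulate_genealogy(scen4, c(N = 500), c(A = 2)),
               class = "domain_error")
})

test_that("prior draws respect conditions and flag impossible priors", {
  pr <- list(t1 = prior_unif(10, 100), t2 = prior_unif(10, 100))
  set.seed(2)
  for (i in 1:20) {
    par <- draw_params(pr, "t1 > t2")
    expect_gt(par["t1"], par["t2"])
  }
  bad <- list(t1 = prior_unif(1, 2), t2 = prior_unif(10, 20))
  expect_error(draw_params(bad, "t1 > t2", max_tries = 50),
               class = "prior_inconsistency_error")
  # log-uniform draws stay inside bounds
  lu <- replicate(200, draw_params(list(x = prior_logunif(1e-8, 1e-4)))["x"])
  expect_true(all(lu >= 1e-8 & lu <= 1e-4))
})

test_that("sequence mutation respects model limits", {
  set.seed(3)
  tr <- simulate_genealogy(one_pop(200), c(), c(A = 8), ploidy = "mtdna")
  m <- subst_model("HKY", gamma_shape = Inf, prop_invariant = 0, kappa = 2)
  a0 <- mutate_sequence(tr, m, 100, 0)
  expect_equal(length(unique(a0$seqs)), 1)   # zero rate: identical

  # kappa -> Inf: transversions absent on a two-leaf tree
  m_ti <- subst_model("HKY", gamma_shape = Inf, prop_invariant = 0,
                      kappa = 1e9)
  pur <- c("A" = "G", "G" = "A", "C" = "T", "T" = "C")
  for (r in 1:20) {
    tr2 <- simulate_genealogy(one_pop(500), c(), c(A = 2), ploidy = "mtdna")
    a <- mutate_sequence(tr2, m_ti, 200, 5e-5)
    x <- strsplit(a$seqs[1], "")[[1]]; y <- strsplit(a$seqs[2], "")[[1]]
    d <- which(x != y)
    expect_true(all(y[d] == pur[x[d]]))
  }
})

test_that("microsatellite mutation follows the generalized stepwise model", {
  set.seed(4)
  # strict stepwise limit: allele sizes move in single motif units
  sizes <- unlist(lapply(1:40, function(i) {
    tr <- simulate_genealogy(one_pop(500), c(), c(A = 2))
    mutate_microsat(tr, 1e-3, P = 1, motif = 3L)
  }))
  expect_true(all((sizes - 100) %% 3 == 0))
  expect_true(all(sizes >= 100 & sizes <= 100 + 3 * 39))

  # zero rate: monomorphic
  tr <- simulate_genealogy(one_pop(500), c(), c(A = 10))
  expect_equal(length(unique(mutate_microsat(tr, 0, 0.5, 4L))), 1)

  # symmetric steps: mean signed displacement near 0
  disp <- replicate(400, {
    tr <- simulate_genealogy(one_pop(2000), c(), c(A = 2))
    sz <- mutate_microsat(tr, 5e-4, 0.3, 4L)
    sz[1] - sz[2]
  })
  se <- sd(disp) / sqrt(length(disp))
  expect_lt(abs(mean(disp)), 3 * se + 1e-9)
})

test_that("summary statistics match hand computation on a toy fixture", {
  # monomorphic sequence data
  ds0 <- islandpop:::seq_dataset(matrix(integer(0), 4, 0), 100,
                                 c("A", "A", "B", "B"))
  st0 <- summary_stats(ds0)
  expect_equal(unname(st0["pool_S"]), 0)
  expect_equal(unname(st0["pool_pi"]), 0)
  expect_equal(unname(st0["pool_tajD"]), 0)   # degenerate -> 0

  # two samples from one panmictic pool: pairwise fst ~ 0
  set.seed(77)
  states <- matrix(sample(1:4, 40 * 30, TRUE), 40)
  ds1 <- islandpop:::seq_dataset(states, 60, rep(c("A", "B"), 20))
  st1 <- summary_stats(ds1)
  expect_lt(abs(st1[["pair_A_B_fst"]]), 0.05)

  # microsatellite toy: one locus, two pops of two diploids
  loci <- list(rbind(c(100, 104), c(100, 100), c(108, 108), c(104, 108)))
  ds2 <- islandpop:::msat_dataset(loci, c("A", "A", "B", "B"),
                                  motif = 4L)
  st2 <- summary_stats(ds2)
  # pop A copies {100,104,100,100}: 2 alleles, Hs = 4/3*(1-(9+1)/16)
  expect_equal(unname(st2["A_meanA"]), 2)
  expect_equal(unname(st2["A_meanHs"]), 4 / 3 * (1 - 10 / 16))
  expect_equal(unname(st2["A_sizevar"]), var(c(100, 104, 100, 100)))
  # (delta mu)^2 = ((101 - 107)/4)^2
  expect_equal(unname(st2["pair_A_B_dmu2"]),
               ((mean(c(100, 104, 100, 100)) -
                   mean(c(108, 108, 104, 108))) / 4)^2)
  # shared-allele distance: shared mins = min(.75,0)+min(.25,.25)+min(0,.75)
  expect_equal(unname(st2["pair_A_B_das"]), 1 - 0.25)
  # WC theta on the same data equals the estimator route
  g <- make_genotypes(c("A", "A", "B", "B"),
                      matrix(c(100L, 100L, 108L, 104L), 4),
                      matrix(c(104L, 100L, 108L, 108L), 4))
  fs <- wc_fstats(g, "site", n_boot = 0)
  expect_equal(unname(st2["pair_A_B_fst"]), unname(fs$overall["FST"]))
})

test_that("reference tables are balanced, conditioned and monotone", {
  scens <- list(s1 = one_pop(500), s2 = one_pop(5000))
  pr <- list(x = prior_unif(0, 1))
  cfg <- sim_config_seq(c(A = 12), mu = 2e-6)
  ref <- build_reference_table(scens, pr, cfg, n_sim = 100, seed = 1)
  expect_equal(nrow(ref), 200)
  expect_equal(as.integer(table(ref$scenario)), c(100L, 100L))
  expect_false(anyNA(ref[, attr(ref, "stat_names")]))
  # larger Ne -> more segregating sites
  expect_gt(mean(ref$pool_S[ref$scenario == "s2"]),
            mean(ref$pool_S[ref$scenario == "s1"]))

  # conditions respected in every retained draw
  scen_c <- scenario("c", "A", list(A = "N"),
                     list(event_size("t2", "A", 100),
                          event_size("t1", "A", "N")),
                     conditions = "t1 > t2")
  ref2 <- build_reference_table(
    list(c = scen_c),
    list(N = prior_unif(100, 1000), t1 = prior_unif(10, 1000),
         t2 = prior_unif(10, 1000)),
    cfg, n_sim = 100, seed = 2)
  expect_true(all(ref2$t1 > ref2$t2))
})

test_that("scenario choice is symmetric for identical scenarios", {
  scens <- list(a = one_pop(2000), b = one_pop(2000))
  pr <- list(x = prior_unif(0, 1))
  cfg <- sim_config_seq(c(A = 15), mu = 1e-6)
  ref <- build_reference_table(scens, pr, cfg, n_sim = 600, seed = 3)
  set.seed(30)
  post <- replicate(12, {
    obs <- summary_stats(simulate_dataset(scens$a, c(x = 0.5), cfg))
    scenario_choice(ref, obs, delta = 0.05)$posterior["a"]
  })
  expect_equal(mean(post), 0.5, tolerance = 0.06)
  one <- scenario_choice(ref,
                         summary_stats(simulate_dataset(scens$a,
                                                        c(x = 0.5), cfg)),
                         delta = 0.05)
  expect_equal(sum(one$posterior), 1, tolerance = 1e-9)
  expect_error(scenario_choice(ref[ref$scenario == "a", ],
                               summary_stats(simulate_dataset(
                                 scens$a, c(x = 0.5), cfg))),
               class = "domain_error")
})

test_that("parameter estimation concentrates, bounds and falls back", {
  # hand-built reference table with a noiseless monotone statistic
  set.seed(5)
  n <- 3000
  theta <- runif(n, 0, 10)
  ref <- data.frame(scenario = "m", theta = theta,
                    s1 = theta^2,              # invertible map
                    s2 = rnorm(n))             # uninformative noise
  attr(ref, "stat_names") <- c("s1", "s2")
  attr(ref, "param_names") <- "theta"
  class(ref) <- c("reference_table", "data.frame")
  pr <- list(theta = prior_unif(0, 10))
  obs <- c(s1 = 36, s2 = 0)                    # f^{-1}(36) = 6
  est <- estimate_parameters(ref, obs, "m", pr, delta = 0.02)
  expect_equal(unname(est$quantiles["theta", "q50"]), 6,
               tolerance = 0.2 / 6)            # within 2% of the range
  expect_true(all(est$adjusted$theta >= 0 & est$adjusted$theta <= 10))

  # statistic independent of the parameter: posterior ~ prior
  ref2 <- data.frame(scenario = "m", theta = theta, s1 = rnorm(n))
  attr(ref2, "stat_names") <- "s1"
  attr(ref2, "param_names") <- "theta"
  class(ref2) <- c("reference_table", "data.frame")
  est2 <- estimate_parameters(ref2, c(s1 = 0), "m", pr, delta = 0.2)
  ks <- suppressWarnings(ks.test(est2$adjusted$theta, "punif", 0, 10))
  expect_lt(unname(ks$statistic), 0.1)

  expect_error(estimate_parameters(ref[1:50, ], obs, "m", pr),
               class = "domain_error")
})

test_that("pods validation reports symmetric confusion for identical models", {
  scens <- list(a = one_pop(2000), b = one_pop(2000))
  pr <- list(x = prior_unif(0, 1))
  cfg <- sim_config_seq(c(A = 12), mu = 1e-6)
  ref <- build_reference_table(scens, pr, cfg, n_sim = 400, seed = 6)
  pods <- suppressWarnings(
    pods_validation(ref, scens, pr, cfg, n_pods = 30, delta = 0.05,
                    seed = 7))
  expect_equal(unname(rowSums(pods$confusion)), c(1, 1))
  expect_equal(mean(pods$misclassification), 0.5, tolerance = 0.2)
})

test_that("posterior predictive checks calibrate and flag misfit", {
  scen <- scenario("m", "A", list(A = "Ne"), list())
  pr <- list(Ne = prior_logunif(200, 50000))
  cfg <- sim_config_seq(c(A = 15), mu = 1e-6)
  ref <- build_reference_table(list(m = scen), pr, cfg, n_sim = 1500,
                               seed = 8)
  used <- c("pool_S", "pool_pi", "pool_nhap")
  hold <- c("pool_Hd", "pool_tajD")
  set.seed(80)
  obs <- summary_stats(simulate_dataset(scen, c(Ne = 5000), cfg))
  post <- estimate_parameters(ref, obs, "m", pr, delta = 0.05,
                              stats = used)
  mc <- model_check(scen, post, obs, hold, cfg, n_sim = 300, seed = 9)
  expect_true(all(mc$tail_prob > 0.01 & mc$tail_prob < 0.99))

  # grossly different truth (10x Ne beyond the prior's reach of the fit)
  obs_bad <- summary_stats(simulate_dataset(scen, c(Ne = 2e6), cfg))
  mc_bad <- model_check(scen, post, obs_bad, hold, cfg, n_sim = 300,
                        seed = 10)
  expect_true(any(mc_bad$tail_prob > 0.99 | mc_bad$tail_prob < 0.01))

  expect_error(model_check(scen, post, obs, character(0), cfg),
               class = "domain_error")
  expect_error(model_check(scen, post, obs, "pool_S", cfg),
               class = "domain_error")
})

test_that("allele-size divergence saturates across deep splits (homoplasy)", {
  # under the bounded stepwise model, alleles identical in size but not
  # by descent accumulate with split depth, so the (delta mu)^2
  # distance stops growing with time: divergence across a 10x deeper
  # split barely exceeds a deep split, while in the pre-saturation
  # regime the same 10x time factor multiplies the distance
  mk <- function(t_split) scenario(
    "two", c("A", "B"), list(A = 2000, B = 2000),
    list(event_merge(t_split, "B", "A")))
  cfg <- sim_config_msat(c(A = 15, B = 15), n_loci = 8, mu = 5e-4)
  set.seed(55)
  mean_dmu2 <- vapply(c(t1 = 2e3, t2 = 2e4, t3 = 2e5, t4 = 2e6),
                      function(ts) {
    mean(replicate(30, summary_stats(
      simulate_dataset(mk(ts), c(), cfg))[["pair_A_B_dmu2"]]))
  }, numeric(1))
  # pre-saturation: strong growth; saturated: near plateau
  expect_gt(mean_dmu2[["t2"]] / mean_dmu2[["t1"]], 2.5)
  expect_lt(mean_dmu2[["t4"]] / mean_dmu2[["t3"]], 1.5)
})

test_that("a YAML scenario configuration round-trips into the simulator", {
  path <- system.file("extdata", "composite_model.yaml",
                      package = "islandpop")
  cfg <- read_scenario_config(path)
  expect_named(cfg$scenarios, "composite")
  expect_s3_class(cfg$scenarios$composite, "scenario")
  expect_length(cfg$scenarios$composite$events, 14)
  expect_s3_class(cfg$priors$Ne, "prior")
  set.seed(9)
  par <- draw_params(cfg$priors, cfg$scenarios$composite$conditions,
                     max_tries = 1000)
  expect_gt(par["t_north"], par["t_cs"])
  ds <- simulate_dataset(cfg$scenarios$composite, par, cfg$config)
  st <- summary_stats(ds)
  expect_false(anyNA(st))
  expect_true("pair_bp_north_fst" %in% names(st))
})
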