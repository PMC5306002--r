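# ABC engine: reference tables of simulated summary statistics,
# scenario choice by LDA projection + multinomial logistic regression,
# local-linear posterior parameter estimation with logit transformation,
# pseudo-observed-dataset validation, and posterior predictive checks.

#' Simulation configuration for a marker
#'
#' @param samples Named vector: sequences (seq) or diploid individuals
#'   (msat) sampled per population.
#' @param length Sequence length in bp.
#' @param model A [subst_model()] for the mutation process (HKY fields).
#' @param mu Mutation rate per site (seq) or per locus (msat) per
#'   generation; ignored when the priors provide `mu_seq` / `mu_msat`.
#' @param freq Stationary base frequencies.
#' @return A config list consumed by [simulate_dataset()].
#' @export
sim_config_seq <- function(samples, length = 491L,
                           model = subst_model("HKY", gamma_shape = 0.78,
                                               prop_invariant = 0.61,
                                               kappa = 4),
                           mu = 1e-6, freq = rep(0.25, 4)) {
  list(type = "seq", samples = samples, length = length, model = model,
       mu = mu, freq = freq, ploidy = "mtdna")
}

#' @rdname sim_config_seq
#' @param n_loci Number of microsatellite loci.
#' @param motif Motif lengths (bp), recycled over loci.
#' @param P Geometric step parameter of the generalized stepwise model.
#' @param rate_shape Gamma shape of among-locus rate spread (Inf = all
#'   loci at the mean rate).
#' @param range_units Contiguous allele states per locus.
#' @export
sim_config_msat <- function(samples, n_loci = 8L, motif = 4L, P = 0.22,
                            mu = 5e-4, rate_shape = Inf,
                            range_units = 40L) {
  list(type = "msat", samples = samples, n_loci = n_loci,
       motif = rep_len(motif, n_loci), P = P, mu = mu,
       rate_shape = rate_shape, range_units = range_units,
       ploidy = "diploid")
}

#' Simulate one dataset under a scenario
#'
#' Draws the genealogy with [simulate_genealogy()] and mutations with
#' [mutate_sequence()] (internally, at segregating sites only) or
#' [mutate_microsat()], honoring `mu_seq` / `mu_msat` / `P_msat`
#' parameters when present in `params`.
#'
#' @param scen A [scenario()].
#' @param params Named parameter vector.
#' @param config A [sim_config_seq()] or [sim_config_msat()].
#' @return An `abc_dataset`.
#' @export
simulate_dataset <- function(scen, params, config) {
  if (config$type == "seq") {
    mu <- if ("mu_seq" %in% names(params)) params[["mu_seq"]] else config$mu
    tree <- simulate_genealogy(scen, params, config$samples,
                               ploidy = "mtdna")
    sim <- sim_seq_states(tree, config$model, config$length, mu,
                          config$freq)
    seq_dataset(sim$states, config$length, tree$leaf_pop)
  } else {
    mu_bar <- if ("mu_msat" %in% names(params)) params[["mu_msat"]] else
      config$mu
    P <- if ("P_msat" %in% names(params)) params[["P_msat"]] else config$P
    n_ind <- config$samples
    copies <- 2L * n_ind
    loci <- vector("list", config$n_loci)
    rates <- if (is.finite(config$rate_shape))
      mu_bar * rgamma(config$n_loci, config$rate_shape,
                      rate = config$rate_shape)
    else rep(mu_bar, config$n_loci)
    for (l in seq_len(config$n_loci)) {
      tree <- simulate_genealogy(scen, params, copies, ploidy = "diploid")
      sz <- mutate_microsat(tree, rates[l], P, config$motif[l],
                            config$range_units)
      loci[[l]] <- matrix(sz, ncol = 2, byrow = TRUE)
    }
    pop <- rep(names(n_ind), n_ind)
    msat_dataset(loci, pop, motif = config$motif,
                 range_units = config$range_units)
  }
}

#' Build an ABC reference table
#'
#' Draws parameters from the priors (with condition rejection),
#' simulates a dataset per draw, and records (scenario id, parameters,
#' summary statistics) rows. Reproducible under `seed`.
#'
#' @param scenarios Named list of [scenario()] objects.
#' @param priors Either one named list of priors shared by all
#'   scenarios, or a named list (per scenario) of such lists.
#' @param config Marker configuration ([sim_config_seq()] /
#'   [sim_config_msat()]).
#' @param n_sim Simulations per scenario (>= 100).
#' @param seed Seed.
#' @param progress_every Log a progress message every this many rows
#'   (0 = silent).
#' @return A data frame of class `reference_table` with columns
#'   `scenario`, the union of parameter names, and the statistics;
#'   attributes `stat_names` and `param_names`.
#' @export
build_reference_table <- function(scenarios, priors, config, n_sim,
                                  seed = 1L, progress_every = 0L) {
  if (n_sim < 100) stop_islandpop("n_sim must be >= 100", "domain_error")
  shared <- all(vapply(priors, inherits, logical(1), "prior"))
  get_priors <- function(nm) if (shared) priors else priors[[nm]]
  set.seed(seed)
  rows <- vector("list", length(scenarios) * n_sim)
  ri <- 0L
  for (nm in names(scenarios)) {
    pr <- get_priors(nm)
    scen <- scenarios[[nm]]
    for (s in seq_len(n_sim)) {
      par <- draw_params(pr, scen$conditions)
      ds <- simulate_dataset(scen, par, config)
      st <- summary_stats(ds)
      ri <- ri + 1L
      rows[[ri]] <- c(list(scenario = nm), as.list(par), as.list(st))
      if (progress_every > 0 && ri %% progress_every == 0)
        message("reference table: ", ri, " rows")
    }
  }
  param_names <- unique(unlist(lapply(names(scenarios), function(nm)
    names(get_priors(nm)))))
  stat_names <- setdiff(names(rows[[1]]), c("scenario", param_names))
  df <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(param_names, names(r))
    for (m in miss) r[[m]] <- NA_real_
    as.data.frame(r[c("scenario", param_names, stat_names)])
  }))
  attr(df, "stat_names") <- stat_names
  attr(df, "param_names") <- param_names
  class(df) <- c("reference_table", "data.frame")
  df
}

ref_stats_matrix <- function(ref, stats = NULL) {
  sn <- stats %||% attr(ref, "stat_names")
  as.matrix(ref[, sn, drop = FALSE])
}

# fit the LDA projection + standardization used for scenario choice
sc_fit <- function(ref, stats = NULL) {
  X <- ref_stats_matrix(ref, stats)
  keep <- apply(X, 2, function(v) sd(v) > 1e-12)
  X <- X[, keep, drop = FALSE]
  lab <- factor(ref$scenario)
  fit <- robust_lda(X, lab)
  proj <- X %*% fit$scaling
  mu <- colMeans(proj); sdv <- apply(proj, 2, sd)
  sdv[sdv < 1e-12] <- 1
  # shuffle rows with a fixed permutation so that distance ties (common
  # with discrete statistics) are broken evenly across scenarios
  rs <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                    .GlobalEnv) else NULL
  set.seed(285714L)
  perm <- sample.int(nrow(X))
  if (!is.null(rs)) assign(".Random.seed", rs, .GlobalEnv) else
    rm(".Random.seed", envir = .GlobalEnv)
  Z <- sweep(sweep(proj, 2, mu), 2, sdv, "/")
  list(lda = fit, keep = keep, mu = mu, sd = sdv,
       Z = Z[perm, , drop = FALSE], lab = lab[perm],
       stat_names = colnames(X))
}

sc_classify <- function(fit, observed, delta = 0.01, n_ci = 500L,
                        ci_seed = 1L) {
  obs <- observed[fit$stat_names]
  if (anyNA(obs)) stop_islandpop("observed stats missing entries",
                                 "domain_error")
  z_obs <- (drop(matrix(obs, 1) %*% fit$lda$scaling) - fit$mu) / fit$sd
  d <- sqrt(colSums((t(fit$Z) - z_obs)^2))
  n_keep <- max(20L, ceiling(delta * length(d)))
  # include every row tied with the cutoff distance so that ties
  # (common with discrete statistics) cannot skew the scenario mix
  dcut <- sort(d)[n_keep]
  idx <- which(d <= dcut + 1e-12)
  n_keep <- length(idx)
  lab <- droplevels(fit$lab[idx])
  lev_all <- levels(fit$lab)
  post <- setNames(rep(0, length(lev_all)), lev_all)
  ci <- matrix(NA_real_, 2, length(lev_all),
               dimnames = list(c("lo", "hi"), lev_all))
  if (nlevels(lab) == 1) {
    post[levels(lab)] <- 1
    ci[, levels(lab)] <- c(1, 1)
    ci[is.na(ci)] <- 0
    warning("only one scenario among retained simulations")
    return(list(posterior = post, ci = ci, n_retained = n_keep))
  }
  D <- sweep(fit$Z[idx, , drop = FALSE], 2, z_obs)  # axis differences
  dat <- data.frame(lab = lab, D)
  capture.output(mfit <- nnet::multinom(lab ~ ., data = dat,
                                        maxit = 300, trace = FALSE))
  nd <- as.data.frame(matrix(0, 1, ncol(D)))
  names(nd) <- colnames(dat)[-1]
  p0 <- predict(mfit, newdata = nd, type = "probs")
  if (is.null(dim(p0))) p0 <- setNames(c(1 - p0, p0), levels(lab))
  post[names(p0)] <- p0
  # CI by sampling from the asymptotic normal of the coefficients
  cf <- coef(mfit)
  V <- tryCatch(vcov(mfit), error = function(e) NULL)
  if (!is.null(V)) {
    # CI simulation uses its own stream; the caller's RNG state is
    # restored afterwards so pods loops stay independent
    rs <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(rs)) assign(".Random.seed", rs, .GlobalEnv),
            add = TRUE)
    set.seed(ci_seed)
    cf_vec <- as.vector(t(cf))
    if (is.null(dim(cf))) cf_vec <- as.vector(cf)
    ch <- tryCatch(chol(V + diag(1e-8, nrow(V))),
                   error = function(e) NULL)
    if (!is.null(ch)) {
      draws <- matrix(rnorm(n_ci * length(cf_vec)), n_ci) %*% ch
      draws <- sweep(draws, 2, cf_vec, "+")
      lv <- levels(lab)
      K <- length(lv)
      sims <- matrix(0, n_ci, K, dimnames = list(NULL, lv))
      for (b in seq_len(n_ci)) {
        if (K == 2) {
          eta <- draws[b, 1]   # intercept of the second level
          p2 <- 1 / (1 + exp(-eta))
          sims[b, ] <- c(1 - p2, p2)
        } else {
          B <- matrix(draws[b, ], nrow = K - 1, byrow = TRUE)
          eta <- B[, 1]
          ex <- c(1, exp(eta))
          sims[b, ] <- ex / sum(ex)
        }
      }
      qs <- apply(sims, 2, quantile, c(0.025, 0.975))
      ci[, colnames(qs)] <- qs
      ci[is.na(ci)] <- 0
    }
  }
  list(posterior = post, ci = ci, n_retained = n_keep)
}

#' ABC scenario choice
#'
#' Summary statistics are projected onto linear discriminant axes
#' trained on the scenario labels of the reference table; among the
#' `delta` fraction of simulations closest (Euclidean on standardized
#' axes) to the observed point, a multinomial logistic regression on
#' the axis offsets predicts the scenario probabilities at the observed
#' point, with 95% CIs from the regression's asymptotic covariance.
#'
#' @param ref A [build_reference_table()] result with >= 2 scenarios.
#' @param observed Named statistic vector ([summary_stats()]).
#' @param delta Fraction of closest simulations retained (0.01).
#' @param stats Optional subset of statistic names to use.
#' @return A list of class `scenario_choice`: `posterior` (sums to 1),
#'   `ci`, `n_retained`.
#' @export
scenario_choice <- function(ref, observed, delta = 0.01, stats = NULL) {
  if (length(unique(ref$scenario)) < 2)
    stop_islandpop("need >= 2 scenarios", "domain_error")
  fit <- sc_fit(ref, stats)
  res <- sc_classify(fit, observed, delta)
  res$stats_used <- fit$stat_names
  class(res) <- "scenario_choice"
  res
}

logit_bound <- function(x, lo, hi) {
  x <- pmin(pmax(x, lo + 1e-12 * (hi - lo)), hi - 1e-12 * (hi - lo))
  log((x - lo) / (hi - x))
}
inv_logit_bound <- function(y, lo, hi) lo + (hi - lo) / (1 + exp(-y))

#' ABC posterior parameter estimation
#'
#' Among the `delta` fraction of a scenario's simulations closest to
#' the observed statistics (Euclidean on z-standardized statistics),
#' parameters are logit-transformed to their prior bounds and adjusted
#' by Epanechnikov-weighted local-linear regression on the statistic
#' offsets; posterior quantiles are computed from the back-transformed
#' adjusted values.
#'
#' @param ref Reference table (rows of other scenarios are ignored).
#' @param observed Named statistic vector.
#' @param scenario_id Scenario whose rows to use (default: all rows).
#' @param priors The prior list used to build the table (bounds for the
#'   logit transform).
#' @param delta Retained fraction (0.01).
#' @param stats Optional statistic subset.
#' @return A list of class `abc_posterior`: `quantiles` (2.5/50/97.5%
#'   per parameter), `adjusted` (data frame of adjusted draws),
#'   `weights`, `n_retained`, `stats_used`.
#' @export
estimate_parameters <- function(ref, observed, scenario_id = NULL, priors,
                                delta = 0.01, stats = NULL) {
  rows <- if (is.null(scenario_id)) ref else
    ref[ref$scenario == scenario_id, , drop = FALSE]
  if (nrow(rows) < 100)
    stop_islandpop("too few reference rows for this scenario",
                   "domain_error")
  pn <- names(priors)
  pn <- pn[pn %in% names(rows)]
  X <- ref_stats_matrix(rows, stats %||% attr(ref, "stat_names"))
  keep <- apply(X, 2, function(v) sd(v) > 1e-12)
  X <- X[, keep, drop = FALSE]
  mu <- colMeans(X); sdv <- apply(X, 2, sd)
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  obs <- observed[colnames(X)]
  if (anyNA(obs)) stop_islandpop("observed stats missing entries",
                                 "domain_error")
  z_obs <- (obs - mu) / sdv
  d <- sqrt(colSums((t(Z) - z_obs)^2))
  n_keep <- max(50L, ceiling(delta * nrow(rows)))
  idx <- order(d)[seq_len(n_keep)]
  dmax <- max(d[idx]) * (1 + 1e-9)
  w <- if (dmax > 0) 1 - (d[idx] / dmax)^2 else rep(1, n_keep)
  D <- sweep(Z[idx, , drop = FALSE], 2, z_obs)
  adjusted <- list()
  for (p in pn) {
    b <- prior_bounds(priors[[p]])
    y <- logit_bound(rows[[p]][idx], b[1], b[2])
    fit <- tryCatch(lm(y ~ D, weights = w), error = function(e) NULL)
    if (is.null(fit)) {
      adjusted[[p]] <- inv_logit_bound(y, b[1], b[2])  # rejection only
      next
    }
    cf <- coef(fit)
    cf[is.na(cf)] <- 0
    pred0 <- cf[1]                       # fitted value at offset 0
    yadj <- pred0 + stats::residuals(fit)
    adjusted[[p]] <- inv_logit_bound(yadj, b[1], b[2])
  }
  adjusted <- as.data.frame(adjusted)
  qs <- t(vapply(pn, function(p)
    weighted_quantile(adjusted[[p]], w, c(0.025, 0.5, 0.975)),
    numeric(3)))
  colnames(qs) <- c("q025", "q50", "q975")
  structure(list(quantiles = qs, adjusted = adjusted, weights = w,
                 n_retained = n_keep,
                 stats_used = colnames(X)),
            class = "abc_posterior")
}

#' Pseudo-observed dataset (pods) validation
#'
#' Simulates datasets with known truth under each scenario, classifies
#' them against the reference table, and reports per-scenario
#' misclassification rates; optionally, for one scenario, estimates
#' parameters for each pod and reports 95%-interval coverage and median
#' relative bias.
#'
#' @param ref Reference table.
#' @param scenarios Named scenario list used to build `ref`.
#' @param priors Priors (shared or per scenario) used to build `ref`.
#' @param config Simulation config.
#' @param n_pods Pods per scenario (default 500).
#' @param delta ABC tolerance fraction.
#' @param seed Seed.
#' @param estimate_for Optional scenario name: also run parameter
#'   estimation on that scenario's pods.
#' @param stats Optional statistic subset for the choice step.
#' @return A list of class `pods_report`: `confusion` (matrix of
#'   assignment proportions), `misclassification` per scenario, and
#'   when requested `coverage` and `median_rel_bias` per parameter.
#' @export
pods_validation <- function(ref, scenarios, priors, config,
                            n_pods = 500L, delta = 0.01, seed = 1L,
                            estimate_for = NULL, stats = NULL) {
  shared <- all(vapply(priors, inherits, logical(1), "prior"))
  get_priors <- function(nm) if (shared) priors else priors[[nm]]
  fit <- sc_fit(ref, stats)
  lev <- levels(factor(ref$scenario))
  conf <- matrix(0, length(lev), length(lev),
                 dimnames = list(true = lev, assigned = lev))
  set.seed(seed)
  cover <- NULL; bias <- NULL
  for (nm in names(scenarios)) {
    pr <- get_priors(nm)
    for (s in seq_len(n_pods)) {
      par <- draw_params(pr, scenarios[[nm]]$conditions)
      ds <- simulate_dataset(scenarios[[nm]], par, config)
      st <- summary_stats(ds)
      res <- suppressWarnings(sc_classify(fit, st, delta))
      pick <- names(which.max(res$posterior))
      conf[nm, pick] <- conf[nm, pick] + 1
      if (!is.null(estimate_for) && nm == estimate_for) {
        est <- estimate_parameters(ref, st, scenario_id = nm,
                                   priors = pr, delta = delta,
                                   stats = stats)
        hit <- par[rownames(est$quantiles)] >= est$quantiles[, "q025"] &
               par[rownames(est$quantiles)] <= est$quantiles[, "q975"]
        rb <- (est$quantiles[, "q50"] - par[rownames(est$quantiles)]) /
          par[rownames(est$quantiles)]
        cover <- rbind(cover, hit)
        bias <- rbind(bias, rb)
      }
    }
  }
  conf <- conf / n_pods
  out <- list(confusion = conf,
              misclassification = 1 - diag(conf))
  if (!is.null(cover)) {
    out$coverage <- colMeans(cover)
    out$median_rel_bias <- apply(bias, 2, median)
  }
  structure(out, class = "pods_report")
}

#' Posterior predictive model check
#'
#' Simulates datasets from posterior parameter draws and reports, for
#' each held-out statistic, the posterior-predictive tail position of
#' the observed value, `P(sim < obs) + 0.5 P(sim = obs)`, together with
#' the two-tailed probability. Held-out statistics must be disjoint
#' from those used in estimation.
#'
#' @param scen The fitted [scenario()].
#' @param posterior An [estimate_parameters()] result.
#' @param observed Full observed statistic vector.
#' @param holdout Character vector of statistic names not used in
#'   estimation.
#' @param config Simulation config.
#' @param n_sim Posterior predictive simulations (default 500).
#' @param seed Seed.
#' @param fixed_params Named values for scenario parameters absent from
#'   the posterior draws.
#' @return A data frame: `stat`, `tail_prob`, `p_two_tailed`.
#' @export
model_check <- function(scen, posterior, observed, holdout, config,
                        n_sim = 500L, seed = 1L, fixed_params = NULL) {
  if (length(holdout) == 0)
    stop_islandpop("no holdout statistics supplied", "domain_error")
  if (any(holdout %in% posterior$stats_used))
    stop_islandpop("holdout statistics overlap the estimation set",
                   "domain_error")
  set.seed(seed)
  draws <- posterior$adjusted
  sims <- matrix(NA_real_, n_sim, length(holdout),
                 dimnames = list(NULL, holdout))
  for (s in seq_len(n_sim)) {
    row <- draws[sample.int(nrow(draws), 1), , drop = FALSE]
    par <- setNames(as.numeric(row), names(draws))
    par <- c(par, fixed_params[setdiff(names(fixed_params), names(par))])
    st <- summary_stats(simulate_dataset(scen, par, config))
    sims[s, ] <- st[holdout]
  }
  tail_prob <- vapply(holdout, function(h) {
    mean(sims[, h] < observed[h]) + 0.5 * mean(sims[, h] == observed[h])
  }, numeric(1))
  data.frame(stat = holdout, tail_prob = tail_prob,
             p_two_tailed = pmin(1, 2 * pmin(tail_prob, 1 - tail_prob)),
             row.names = NULL)
}
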