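# Structured-coalescent simulation under declared demographic scenarios:
# population trees with splits, size changes and admixture, sequence
# mutation under HKY with gamma rates and invariant sites, and
# generalized stepwise microsatellite mutation.

#' Declare a demographic scenario
#'
#' A scenario is a set of sampled populations with stable effective
#' sizes and a time-ordered (backward in time) list of events: merges
#' (lineages of one population join another), size changes, and
#' admixture (each lineage reassigned to a donor with some
#' probability). Any numeric field may instead name a parameter to be
#' drawn from priors at simulation time. `conditions` are character
#' inequalities over parameter names enforced by rejection.
#'
#' @param name Scenario id.
#' @param pops Character vector of sampled population names.
#' @param Ne Named list of stable effective sizes (numbers or parameter
#'   names), one per population appearing anywhere in the scenario.
#' @param events List built from [event_merge()], [event_size()],
#'   [event_admix()].
#' @param conditions Character vector of parameter inequalities, e.g.
#'   `"t_north > t_cs"`.
#' @return A list of class `scenario`.
#' @export
scenario <- function(name, pops, Ne, events = list(),
                     conditions = character()) {
  structure(list(name = name, pops = pops, Ne = Ne, events = events,
                 conditions = conditions), class = "scenario")
}

#' @rdname scenario
#' @param time Event time in generations (number or parameter name).
#' @param from,to Populations merged (lineages of `from` move to `to`,
#'   backward in time).
#' @export
event_merge <- function(time, from, to)
  list(type = "merge", time = time, from = from, to = to)

#' @rdname scenario
#' @param pop Affected population.
#' @param Ne New effective size looking further back in time.
#' @export
event_size <- function(time, pop, Ne)
  list(type = "size", time = time, pop = pop, Ne = Ne)

#' @rdname scenario
#' @param donors Two donor populations.
#' @param prop Probability a lineage moves to `donors[1]` (else
#'   `donors[2]`).
#' @export
event_admix <- function(time, pop, donors, prop)
  list(type = "admix", time = time, pop = pop, donors = donors,
       prop = prop)

#' Prior distributions for scenario parameters
#'
#' @param min,max Bounds (uniform / log-uniform).
#' @param mean,sd Normal parameters.
#' @return A list of class `prior`.
#' @export
prior_unif <- function(min, max) {
  stopifnot(is.finite(min), is.finite(max), min < max)
  structure(list(dist = "unif", min = min, max = max), class = "prior")
}

#' @rdname prior_unif
#' @export
prior_logunif <- function(min, max) {
  stopifnot(min > 0, min < max, is.finite(max))
  structure(list(dist = "logunif", min = min, max = max), class = "prior")
}

#' @rdname prior_unif
#' @export
prior_norm <- function(mean, sd) {
  stopifnot(is.finite(mean), sd > 0)
  structure(list(dist = "norm", mean = mean, sd = sd), class = "prior")
}

draw_one <- function(pr) {
  switch(pr$dist,
         unif = runif(1, pr$min, pr$max),
         logunif = exp(runif(1, log(pr$min), log(pr$max))),
         norm = rnorm(1, pr$mean, pr$sd))
}

prior_bounds <- function(pr) {
  switch(pr$dist,
         unif = c(pr$min, pr$max),
         logunif = c(pr$min, pr$max),
         norm = c(pr$mean - 6 * pr$sd, pr$mean + 6 * pr$sd))
}

#' Draw a parameter vector from priors subject to ordering conditions
#'
#' @param priors Named list of [prior_unif()]-type priors.
#' @param conditions Character inequalities over the parameter names.
#' @param max_tries Rejection cap; exceeding it (acceptance < 1%)
#'   raises a prior-inconsistency error.
#' @return Named numeric vector.
#' @export
draw_params <- function(priors, conditions = character(),
                        max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    par <- vapply(priors, draw_one, numeric(1))
    ok <- all(vapply(conditions, function(cond)
      isTRUE(eval(parse(text = cond), as.list(par))), logical(1)))
    if (ok) return(par)
  }
  stop_islandpop("condition rejection rate too high: priors inconsistent",
                 "prior_inconsistency_error")
}

resolve_val <- function(x, params) {
  if (is.character(x)) {
    if (!x %in% names(params) || is.na(params[[x]]))
      stop_islandpop(paste("unresolved parameter:", x), "domain_error")
    return(as.numeric(params[[x]]))
  }
  as.numeric(x)
}

# haploid-scaled coalescent size: 2Ne for autosomal diploid loci,
# Ne/2 for maternally inherited haploid mtDNA
scaled_size <- function(Ne, ploidy) {
  switch(ploidy, diploid = 2 * Ne, mtdna = Ne / 2,
         stop_islandpop("unknown ploidy", "domain_error"))
}

#' Simulate a coalescent genealogy under a scenario
#'
#' Continuous-time structured coalescent: within each population, k
#' lineages coalesce pairwise at rate `C(k,2) / N_scaled` per
#' generation, where `N_scaled = 2 Ne` for autosomal diploid loci and
#' `Ne / 2` for mtDNA. Events are applied at their (resolved) times.
#'
#' @param scen A [scenario()].
#' @param params Named numeric vector resolving the scenario's
#'   parameter names.
#' @param samples Named integer vector: gene copies sampled per
#'   population.
#' @param ploidy `"diploid"` or `"mtdna"` (scaling above).
#' @return A list of class `coal_tree`: `n` leaves, `parent` and `time`
#'   vectors over the `2n - 1` nodes (leaves first, root parent 0), and
#'   `leaf_pop`.
#' @export
simulate_genealogy <- function(scen, params, samples,
                               ploidy = c("diploid", "mtdna")) {
  ploidy <- match.arg(ploidy)
  if (any(samples < 1)) stop_islandpop("need >= 1 sample per listed pop",
                                       "domain_error")
  n <- sum(samples)
  leaf_pop <- rep(names(samples), samples)
  # resolved sizes and events
  allpops <- unique(c(names(scen$Ne), names(samples)))
  sizes <- vapply(allpops, function(p) {
    v <- scen$Ne[[p]]
    if (is.null(v)) stop_islandpop(paste("no Ne for pop", p),
                                   "scenario_validity_error")
    scaled_size(resolve_val(v, params), ploidy)
  }, numeric(1))
  evs <- lapply(scen$events, function(e) {
    e$time <- resolve_val(e$time, params)
    if (e$type == "size") e$Ne_num <- scaled_size(resolve_val(e$Ne, params),
                                                  ploidy)
    if (e$type == "admix") e$prop <- resolve_val(e$prop, params)
    e
  })
  evs <- evs[order(vapply(evs, `[[`, numeric(1), "time"))]

  parent <- integer(2 * n - 1)
  ntime <- numeric(2 * n - 1)
  active <- split(seq_len(n), leaf_pop)           # lineage ids per pop
  for (p in setdiff(allpops, names(active))) active[[p]] <- integer(0)
  nxt <- n + 1L
  t <- 0
  ei <- 1L
  total_active <- n
  repeat {
    if (total_active == 1L) break
    te <- if (ei <= length(evs)) evs[[ei]]$time else Inf
    # coalesce within the current interval
    repeat {
      k <- vapply(active, length, integer(1))
      rates <- ifelse(k >= 2, k * (k - 1) / 2 / sizes[names(active)], 0)
      R <- sum(rates)
      if (R == 0) { t <- te; break }
      dt <- rexp(1, R)
      if (t + dt > te) { t <- te; break }
      t <- t + dt
      p <- sample(names(active), 1, prob = rates)
      pick <- sample(active[[p]], 2)
      parent[pick] <- nxt
      ntime[nxt] <- t
      active[[p]] <- c(setdiff(active[[p]], pick), nxt)
      nxt <- nxt + 1L
      total_active <- total_active - 1L
      if (total_active == 1L) break
    }
    if (total_active == 1L) break
    if (!is.finite(te)) {
      stop_islandpop(
        "lineages stranded in populations with no ancestral merge",
        "scenario_validity_error")
    }
    e <- evs[[ei]]
    ei <- ei + 1L
    if (e$type == "merge") {
      active[[e$to]] <- c(active[[e$to]], active[[e$from]])
      active[[e$from]] <- integer(0)
    } else if (e$type == "size") {
      sizes[e$pop] <- e$Ne_num
    } else if (e$type == "admix") {
      lin <- active[[e$pop]]
      if (length(lin)) {
        go1 <- runif(length(lin)) < e$prop
        active[[e$donors[1]]] <- c(active[[e$donors[1]]], lin[go1])
        active[[e$donors[2]]] <- c(active[[e$donors[2]]], lin[!go1])
        active[[e$pop]] <- integer(0)
      }
    }
  }
  structure(list(n = n, parent = parent, time = ntime,
                 leaf_pop = leaf_pop), class = "coal_tree")
}

# children lists from a parent vector
tree_children <- function(tree) {
  ch <- vector("list", 2 * tree$n - 1)
  for (v in seq_len(2 * tree$n - 2))
    ch[[tree$parent[v]]] <- c(ch[[tree$parent[v]]], v)
  ch
}

# HKY single-mutation jump distribution: from state i, to j with
# probability proportional to (kappa for transitions) * pi_j
hky_jump_matrix <- function(kappa, freq) {
  # states A, C, G, T; transitions A<->G, C<->T
  Q <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    ti <- (i == 1 && j == 3) || (i == 3 && j == 1) ||
      (i == 2 && j == 4) || (i == 4 && j == 2)
    Q[i, j] <- freq[j] * if (ti) kappa else 1
  }
  Q / rowSums(Q)
}

# Simulate mutated states at hit sites only. Returns list(sites, states
# (n x nhit integer 1..4), root_states, L).
sim_seq_states <- function(tree, model, length, mu,
                           freq = rep(0.25, 4)) {
  n <- tree$n
  # per-site rate multipliers: 0 w.p. prop_invariant, else gamma(shape)
  r <- numeric(length)
  varying <- runif(length) >= model$prop_invariant
  if (is.finite(model$gamma_shape))
    r[varying] <- rgamma(sum(varying), model$gamma_shape,
                         rate = model$gamma_shape)
  else r[varying] <- 1
  nb <- seq_len(2L * n - 2L)                   # root excluded
  blen <- tree$time[tree$parent[nb]] - tree$time[nb]
  sumr <- sum(r)
  M <- rpois(1, mu * sum(blen) * sumr)
  if (M == 0 || sumr == 0)
    return(list(sites = integer(0),
                states = matrix(integer(0), n, 0), L = length))
  br <- sample.int(2L * n - 2L, M, replace = TRUE, prob = blen)
  st <- sample.int(length, M, replace = TRUE, prob = r)
  sites <- sort(unique(st))
  site_idx <- match(st, sites)
  jump <- hky_jump_matrix(model$kappa, freq)
  # preorder traversal applying each branch's mutations
  ch <- tree_children(tree)
  root <- 2L * n - 1L
  nhit <- length(sites)
  root_states <- sample.int(4, nhit, replace = TRUE, prob = freq)
  states <- matrix(0L, n, nhit)
  # mutations per branch, in random order along the branch
  mut_by_branch <- split(site_idx, br)
  stack <- list(list(node = root, seq = root_states))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (child in ch[[top$node]]) {
      s <- top$seq
      muts <- mut_by_branch[[as.character(child)]]
      if (!is.null(muts)) {
        for (m in muts[sample.int(length(muts))]) {
          s[m] <- sample.int(4, 1, prob = jump[s[m], ])
        }
      }
      if (child <= n) states[child, ] <- s
      else stack[[length(stack) + 1L]] <- list(node = child, seq = s)
    }
  }
  list(sites = sites, states = states, L = length)
}

#' Drop sequence mutations on a genealogy (HKY + gamma + invariant)
#'
#' Per site the rate is 0 with probability `prop_invariant`, else a
#' gamma(shape)-distributed multiplier; mutation counts are Poisson
#' along branches and each mutation applies an HKY jump (transition
#' bias `kappa`, stationary frequencies `freq`).
#'
#' @param tree A [simulate_genealogy()] tree (branch lengths in
#'   generations).
#' @param model A [subst_model()] (HKY fields used).
#' @param length Sequence length in bp (default 491).
#' @param mu Mutation rate per site per generation.
#' @param freq Stationary base frequencies (A, C, G, T).
#' @return An [ep_alignment()] with ids `<pop>_<i>` and labels = leaf
#'   populations.
#' @export
mutate_sequence <- function(tree, model, length = 491L, mu,
                            freq = rep(0.25, 4)) {
  sim <- sim_seq_states(tree, model, length, mu, freq)
  bases <- c("A", "C", "G", "T")
  n <- tree$n
  backbone <- sample(bases, length, replace = TRUE, prob = freq)
  seqs <- vapply(seq_len(n), function(i) {
    s <- backbone
    if (base::length(sim$sites)) s[sim$sites] <- bases[sim$states[i, ]]
    paste(s, collapse = "")
  }, character(1))
  ids <- paste0(tree$leaf_pop, "_", stats::ave(seq_len(n), tree$leaf_pop,
                                               FUN = seq_along))
  ep_alignment(ids, seqs, labels = setNames(tree$leaf_pop, ids))
}

#' Drop generalized-stepwise microsatellite mutations on a genealogy
#'
#' Mutations are Poisson along branches; each changes the repeat count
#' by a geometric(P) magnitude (P = 1 gives strict stepwise) with
#' random sign, reflected at the boundaries of a contiguous
#' `range_units`-state window.
#'
#' @param tree A [simulate_genealogy()] tree.
#' @param mu Mutation rate per generation.
#' @param P Geometric parameter of the step-size distribution.
#' @param motif Repeat motif length in bp (allele size = `offset +
#'   motif * repeats`).
#' @param range_units Number of contiguous repeat states (default 40).
#' @param offset Base allele size in bp at repeat state 0.
#' @return Integer vector of allele sizes (bp) per leaf, with the leaf
#'   populations as names.
#' @export
mutate_microsat <- function(tree, mu, P = 0.22, motif = 4L,
                            range_units = 40L, offset = 100L) {
  n <- tree$n
  nb <- seq_len(2L * n - 2L)
  blen <- tree$time[tree$parent[nb]] - tree$time[nb]
  counts <- rpois(2L * n - 2L, mu * blen)
  ch <- tree_children(tree)
  root <- 2L * n - 1L
  start <- range_units %/% 2L
  out <- integer(n)
  stack <- list(list(node = root, st = start))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (child in ch[[top$node]]) {
      s <- top$st
      m <- counts[child]
      if (m > 0) {
        for (i in seq_len(m)) {
          step <- (rgeom(1, P) + 1L) * sample(c(-1L, 1L), 1)
          s <- s + step
          # reflect into [0, range_units - 1]
          while (s < 0 || s > range_units - 1L) {
            if (s < 0) s <- -s
            if (s > range_units - 1L) s <- 2L * (range_units - 1L) - s
          }
        }
      }
      if (child <= n) out[child] <- s
      else stack[[length(stack) + 1L]] <- list(node = child, st = s)
    }
  }
  setNames(offset + motif * out, tree$leaf_pop)
}
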