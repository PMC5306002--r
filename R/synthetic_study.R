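# Synthetic two-marker study generator: a 13-site, 3-region island
# system with one haploid 491-bp sequence locus and 8 microsatellite
# loci, simulated under a hierarchical divergence scenario with
# bottlenecks at the splits, plus ground truth for recovery tests.

#' Default site table of the synthetic study
#'
#' Thirteen montane stream sites in three regions (North/Central/South)
#' with per-site sample sizes for each marker; coordinates and
#' altitudes are representative of an east-Sardinian montane system.
#'
#' @return An `ep_sites` data frame.
#' @export
default_sites <- function() {
  df <- data.frame(
    code = c("HP", "BIA", "AFF", "MO", "BP", "PGC", "SES", "PF",
             "MAR", "LNR", "GUN", "MAI", "CER"),
    name = c("Historical Pool", "Fica Bianca", "Affluente Pisciaroni",
             "Monte Olia", "Bacu su Palu", "Grotta dei Colombi",
             "Riu Serra e Scova", "Perdas de Fogu", "Rio Marani",
             "Late Night Return", "Rio su Gunventu", "Rio Maidopis",
             "Rio sa Ceraxa"),
    region = c(rep("North", 4), rep("Central", 4), rep("South", 5)),
    lat = c(40.856, 40.842, 40.862, 40.744, 40.180, 40.172, 39.974,
            39.603, 39.348, 39.352, 39.301, 39.302, 39.272),
    lon = c(9.142, 9.114, 9.143, 9.363, 9.559, 9.491, 9.495, 9.491,
            9.441, 9.447, 9.406, 9.404, 9.442),
    altitude = c(905, 983, 787, 461, 337, 597, 854, 480, 162, 279,
                 421, 715, 535),
    n_msat = c(23L, 14L, 6L, 1L, 16L, 2L, 17L, 15L, 20L, 14L, 15L,
               6L, 19L),
    n_mtdna = c(10L, 10L, 4L, 1L, 9L, 0L, 9L, 8L, 10L, 11L, 10L,
                6L, 8L),
    stringsAsFactors = FALSE)
  class(df) <- c("ep_sites", "data.frame")
  df
}

# site -> demographic deme of the truth scenario
default_deme_map <- function() {
  c(HP = "north", BIA = "north", AFF = "north", MO = "north",
    BP = "bp", PGC = "bp", SES = "ses", PF = "pf",
    MAR = "south", LNR = "lnr", GUN = "south", MAI = "south",
    CER = "south")
}

#' Configuration of the synthetic study
#'
#' The default demographic truth is a hierarchical divergence history
#' over six demes: a deep isolation of the north (~3e6 generations),
#' a center--south split 1.5e4 generations ago, sequential central
#' splits (5e3 and 3e3 generations) and a southern split (3e3
#' generations), each split preceded by a 20-fold bottleneck of
#' duration `db`. The sex-bias knob adds site-level structure to the
#' maternally inherited locus only (female philopatry): site demes
#' isolate `t_site` generations ago for mtDNA while the nuclear loci
#' stay panmictic within demes.
#'
#' @param sites Site table (default [default_sites()]).
#' @param deme_map Named site -> deme assignment.
#' @param Ne Stable effective size per deme (diploid individuals).
#' @param Nb Bottleneck effective size.
#' @param db Bottleneck duration in generations.
#' @param t_north,t_cs,t_ses,t_pf,t_lnr Split times in generations
#'   (backward).
#' @param t_site mtDNA site-isolation age under the sex-bias knob.
#' @param sex_bias Enable female-philopatry site structure for mtDNA.
#' @param mu_seq mtDNA mutation rate /site/generation.
#' @param seq_length Sequence locus length (bp).
#' @param seq_model [subst_model()] for the sequence locus.
#' @param mu_msat Microsatellite mutation rate /locus/generation.
#' @param msat_P Geometric step parameter of the stepwise model.
#' @param msat_motifs Motif lengths (bp) of the 8 loci.
#' @param msat_offsets Base allele size (bp) per locus.
#' @param missing_rate Per-call missingness probability.
#' @return A list of class `study_config`.
#' @export
study_config <- function(sites = default_sites(),
                         deme_map = default_deme_map(),
                         Ne = 5000, Nb = 250, db = 500,
                         t_north = 3e6, t_cs = 1.5e4, t_ses = 5e3,
                         t_pf = 3e3, t_lnr = 3e3, t_site = 2000,
                         sex_bias = TRUE,
                         mu_seq = 6e-7, seq_length = 491L,
                         seq_model = subst_model("HKY",
                                                 gamma_shape = 0.78,
                                                 prop_invariant = 0.61,
                                                 kappa = 4),
                         mu_msat = 2e-4, msat_P = 0.22,
                         msat_motifs = c(4L, 4L, 4L, 4L, 4L, 3L, 4L, 4L),
                         msat_offsets = c(146L, 244L, 168L, 164L, 164L,
                                          180L, 159L, 187L),
                         missing_rate = 0.018) {
  stopifnot(all(sites$n_msat >= 0), t_site < min(t_pf, t_lnr),
            Nb < Ne, db < t_cs)
  structure(as.list(environment()), class = "study_config")
}

# the nuclear (deme-level) truth scenario
truth_scenario_nuclear <- function(cfg) {
  demes <- c("north", "bp", "ses", "pf", "south", "lnr")
  scenario(
    name = "truth",
    pops = demes,
    Ne = as.list(setNames(rep(cfg$Ne, length(demes)), demes)),
    events = list(
      event_size(cfg$t_pf - cfg$db, "pf", cfg$Nb),
      event_size(cfg$t_lnr - cfg$db, "lnr", cfg$Nb),
      event_merge(cfg$t_pf, "pf", "ses"),
      event_merge(cfg$t_lnr, "lnr", "south"),
      event_size(cfg$t_ses - cfg$db, "ses", cfg$Nb),
      event_merge(cfg$t_ses, "ses", "bp"),
      event_size(cfg$t_cs - cfg$db, "south", cfg$Nb),
      event_size(cfg$t_cs - cfg$db, "bp", cfg$Nb),
      event_merge(cfg$t_cs, "south", "bp"),
      event_size(cfg$t_cs, "bp", cfg$Ne),
      event_size(cfg$t_north - cfg$db, "north", cfg$Nb),
      event_size(cfg$t_north - cfg$db, "bp", cfg$Nb),
      event_merge(cfg$t_north, "north", "bp"),
      event_size(cfg$t_north, "bp", cfg$Ne)))
}

# the mtDNA truth scenario: site demes nested in the nuclear demes when
# the sex-bias knob is on
truth_scenario_mtdna <- function(cfg) {
  base <- truth_scenario_nuclear(cfg)
  if (!cfg$sex_bias) return(base)
  sites <- cfg$sites$code
  site_events <- lapply(sites, function(s)
    event_merge(cfg$t_site, s, cfg$deme_map[[s]]))
  Ne <- c(base$Ne, as.list(setNames(rep(cfg$Ne, length(sites)), sites)))
  scenario(name = "truth_mt", pops = sites, Ne = Ne,
           events = c(site_events, base$events))
}

#' Generate a complete synthetic two-marker study
#'
#' Simulates the mtDNA alignment and the 8-locus diploid genotype table
#' under the configured demographic truth, assigns individuals to
#' sites, applies uniform missingness, and returns the ground truth
#' needed for recovery tests.
#'
#' @param cfg A [study_config()].
#' @param seed Integer seed (outputs are byte-identical under a fixed
#'   seed).
#' @return A list of class `synthetic_study`: `alignment`
#'   ([ep_alignment()] of sequenced individuals, labelled by site),
#'   `genotypes` ([ep_genotypes()]), `sites` (`ep_sites`), and `truth`
#'   (parameters, per-individual deme/region, per-haplotype
#'   haplogroup).
#' @export
generate_study <- function(cfg = study_config(), seed = 1L) {
  stopifnot(inherits(cfg, "study_config"))
  scen_nuc <- truth_scenario_nuclear(cfg)
  scen_mt <- truth_scenario_mtdna(cfg)
  set.seed(seed)
  sites <- cfg$sites
  deme <- cfg$deme_map[sites$code]

  # individuals, ordered by deme then site (matches genealogy sampling)
  deme_order <- unique(unname(deme))
  ind <- do.call(rbind, lapply(deme_order, function(d) {
    sc <- sites$code[deme == d]
    do.call(rbind, lapply(sc, function(s) {
      n <- sites$n_msat[sites$code == s]
      if (n == 0) return(NULL)
      data.frame(site = s, region = sites$region[sites$code == s],
                 deme = d, stringsAsFactors = FALSE)[rep(1, n), ]
    }))
  }))
  rownames(ind) <- NULL
  ind$id <- sprintf("%s_%02d", ind$site, stats::ave(seq_len(nrow(ind)),
                                                    ind$site,
                                                    FUN = seq_along))
  ind$sex <- sample(c("M", "F", "unknown"), nrow(ind), replace = TRUE,
                    prob = c(0.4, 0.3, 0.3))
  ind$stage <- sample(c("adult", "larva"), nrow(ind), replace = TRUE,
                      prob = c(0.85, 0.15))

  # nuclear loci: one genealogy per locus over 2n gene copies per deme
  copies <- 2L * table(factor(ind$deme, levels = deme_order))
  copies <- setNames(as.integer(copies), deme_order)
  L <- length(cfg$msat_motifs)
  a1 <- a2 <- matrix(NA_integer_, nrow(ind), L)
  for (l in seq_len(L)) {
    tree <- simulate_genealogy(scen_nuc, c(), copies, ploidy = "diploid")
    sz <- mutate_microsat(tree, cfg$mu_msat, cfg$msat_P,
                          cfg$msat_motifs[l], offset = cfg$msat_offsets[l])
    a1[, l] <- sz[seq(1, length(sz), 2)]
    a2[, l] <- sz[seq(2, length(sz), 2)]
  }
  # uniform missingness per call
  miss <- matrix(runif(nrow(ind) * L) < cfg$missing_rate, nrow(ind), L)
  a1[miss] <- NA; a2[miss] <- NA
  colnames(a1) <- colnames(a2) <-
    paste0("EP", c(1, 7, 8, 16, 21, 29, 31, 33))[seq_len(L)]
  g <- ep_genotypes(ind[, c("id", "site", "region", "sex", "stage")],
                    a1, a2)

  # mtDNA: sequenced subset (first n_mtdna individuals per site)
  seq_ids <- unlist(lapply(sites$code, function(s) {
    n <- sites$n_mtdna[sites$code == s]
    if (n == 0) return(character(0))
    head(ind$id[ind$site == s], n)
  }))
  mt_pop_of <- if (cfg$sex_bias) ind$site else ind$deme
  names(mt_pop_of) <- ind$id
  mt_pops <- mt_pop_of[seq_ids]
  pop_lv <- unique(unname(mt_pops))
  samples_mt <- vapply(pop_lv, function(p) sum(mt_pops == p), integer(1))
  tree <- simulate_genealogy(scen_mt, c(), samples_mt, ploidy = "mtdna")
  aln_raw <- mutate_sequence(tree, cfg$seq_model, cfg$seq_length,
                             cfg$mu_seq)
  # re-id the leaves with the individual ids (leaves grouped by pop in
  # samples_mt order, matching the grouped order of seq_ids)
  ord_ids <- unlist(lapply(pop_lv, function(p) seq_ids[mt_pops == p]))
  aln <- ep_alignment(ord_ids, aln_raw$seqs,
                      labels = setNames(ind$site[match(ord_ids, ind$id)],
                                        ord_ids))
  haps <- collapse_haplotypes(aln)
  hap_region <- vapply(seq_along(haps$haplotypes), function(h) {
    carriers <- aln$ids[haps$assignment == h]
    regs <- ind$region[match(carriers, ind$id)]
    names(sort(table(regs), decreasing = TRUE))[1]
  }, character(1))

  truth <- structure(list(
    params = list(Ne = cfg$Ne, Nb = cfg$Nb, db = cfg$db,
                  t_north = cfg$t_north, t_cs = cfg$t_cs,
                  t_ses = cfg$t_ses, t_pf = cfg$t_pf, t_lnr = cfg$t_lnr,
                  t_site = cfg$t_site, mu_seq = cfg$mu_seq,
                  mu_msat = cfg$mu_msat, sex_bias = cfg$sex_bias),
    individual = data.frame(id = ind$id, site = ind$site,
                            region = ind$region, deme = ind$deme,
                            sequenced = ind$id %in% seq_ids,
                            stringsAsFactors = FALSE),
    haplogroup = setNames(hap_region, haps$hap_ids),
    seed = seed), class = "truth_record")

  structure(list(alignment = aln, genotypes = g, sites = sites,
                 truth = truth, config = cfg),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> ", nrow(x$genotypes$a1), " genotyped, ",
      length(x$alignment$ids), " sequenced, ", nrow(x$sites),
      " sites\n", sep = "")
  invisible(x)
}

#' Write a synthetic study to standard-format files
#'
#' @param study A [generate_study()] result.
#' @param outdir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(outdir, "mtdna.fa"),
             genotypes = file.path(outdir, "genotypes.csv"),
             sites = file.path(outdir, "sites.csv"),
             truth = file.path(outdir, "truth.json"))
  write_alignment(study$alignment, paths["fasta"])
  write_genotypes(study$genotypes, paths["genotypes"])
  write_sites(study$sites, paths["sites"])
  jsonlite::write_json(list(params = study$truth$params,
                            individual = study$truth$individual,
                            haplogroup = as.list(study$truth$haplogroup),
                            seed = study$truth$seed),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Two-level hierarchical allele-frequency generator
#'
#' A simplified Balding--Nichols style generator for validating
#' hierarchical clustering: ancestral allele frequencies drift first
#' into regions (drift `F_region`) and then into subpopulations within
#' regions (drift `F_subpop`); genotypes are drawn in Hardy--Weinberg
#' proportions within subpopulations.
#'
#' @param n_region Regions (top level).
#' @param n_subpop Subpopulations per region.
#' @param n_per_subpop Diploid individuals per subpopulation.
#' @param n_loci,n_alleles Loci and alleles per locus.
#' @param F_region,F_subpop Drift at the two levels.
#' @param seed Seed.
#' @return An [ep_genotypes()] with `site` = subpopulation and `region`
#'   = region.
#' @export
generate_hierarchy <- function(n_region = 2L, n_subpop = 3L,
                               n_per_subpop = 15L, n_loci = 8L,
                               n_alleles = 15L, F_region = 0.25,
                               F_subpop = 0.20, seed = 1L) {
  set.seed(seed)
  rdirichlet1 <- function(alpha) {
    x <- rgamma(length(alpha), alpha)
    x / sum(x)
  }
  n_ind <- n_region * n_subpop * n_per_subpop
  a1 <- a2 <- matrix(NA_integer_, n_ind, n_loci)
  site <- character(n_ind); region <- character(n_ind)
  for (l in seq_len(n_loci)) {
    p_anc <- rdirichlet1(rep(1, n_alleles))
    row <- 0L
    for (r in seq_len(n_region)) {
      p_reg <- rdirichlet1(p_anc * (1 - F_region) / F_region)
      for (s in seq_len(n_subpop)) {
        p_sub <- rdirichlet1(p_reg * (1 - F_subpop) / F_subpop)
        for (i in seq_len(n_per_subpop)) {
          row <- row + 1L
          al <- sample.int(n_alleles, 2, replace = TRUE, prob = p_sub)
          a1[row, l] <- 100L + 2L * al[1]
          a2[row, l] <- 100L + 2L * al[2]
          site[row] <- paste0("R", r, "S", s)
          region[row] <- paste0("R", r)
        }
      }
    }
  }
  meta <- data.frame(id = sprintf("ind%03d", seq_len(n_ind)),
                     site = site, region = region, sex = "unknown",
                     stage = "adult", stringsAsFactors = FALSE)
  colnames(a1) <- colnames(a2) <- paste0("L", seq_len(n_loci))
  ep_genotypes(meta, a1, a2)
}

#' Mitochondrial--nuclear discordance table
#'
#' For each within-region site pair, tests mtDNA differentiation by a
#' permutation test on sequence divergence (Hudson-type statistic,
#' individuals shuffled between the two sites) against the
#' microsatellite pairwise FST permutation test, and reports the
#' concordance pattern. Pairs with fewer than `min_seq` sequenced
#' individuals at either site are flagged untestable.
#'
#' @param aln mtDNA [ep_alignment()] labelled by site.
#' @param g [ep_genotypes()].
#' @param sites Site table.
#' @param n_perm Permutations for both tests (default 999).
#' @param alpha Significance level.
#' @param adjust `"bonferroni"` (default) corrects `alpha` over the
#'   tested pairs; `"none"` applies it per pair.
#' @param min_seq Minimum sequenced individuals per site (default 4).
#' @param seed Seed.
#' @return A data frame: `site1`, `site2`, `region`, `p_mt`, `p_ms`,
#'   `mt_sig`, `ms_sig`, `pattern` (`"sig"`/`"ns"` pairs), `testable`.
#' @export
mito_nuclear_discordance <- function(aln, g, sites, n_perm = 999L,
                                     alpha = 0.05, min_seq = 4L,
                                     adjust = c("bonferroni", "none"),
                                     seed = 1L) {
  adjust <- match.arg(adjust)
  set.seed(seed)
  ds <- as_abc_dataset(aln)
  pairs <- list()
  for (reg in unique(sites$region)) {
    sc <- sites$code[sites$region == reg]
    sc <- sc[sc %in% unique(ds$pop) & sc %in% unique(g$meta$site)]
    if (length(sc) < 2) next
    cmb <- combn(sc, 2)
    for (k in seq_len(ncol(cmb)))
      pairs[[length(pairs) + 1L]] <- c(cmb[, k], reg)
  }
  if (!length(pairs)) stop_islandpop("no testable site pairs",
                                     "domain_error")
  n_tests <- length(pairs)
  res <- lapply(pairs, function(pr) {
    s1 <- pr[1]; s2 <- pr[2]
    n1 <- sum(ds$pop == s1); n2 <- sum(ds$pop == s2)
    testable <- n1 >= min_seq && n2 >= min_seq
    p_mt <- NA_real_
    if (testable) {
      sel <- ds$pop %in% c(s1, s2)
      st <- ds$states[sel, , drop = FALSE]
      pp <- ds$pop[sel]
      fst_obs <- pair_fst_seq(st, pp, s1, s2)
      perm <- vapply(seq_len(n_perm), function(b)
        pair_fst_seq(st, sample(pp), s1, s2), numeric(1))
      p_mt <- (sum(perm >= fst_obs) + 1) / (n_perm + 1)
    }
    sel_g <- g$meta$site %in% c(s1, s2)
    g2 <- ep_genotypes(g$meta[sel_g, ],
                       g$a1[sel_g, , drop = FALSE],
                       g$a2[sel_g, , drop = FALSE], g$loci)
    p_ms <- suppressWarnings(
      pairwise_fst_test(g2, "site", n_perm = n_perm,
                        seed = sample.int(1e6, 1))$p[s1, s2])
    data.frame(site1 = s1, site2 = s2, region = pr[3], p_mt = p_mt,
               p_ms = p_ms, testable = testable,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  thr <- if (adjust == "bonferroni") alpha / n_tests else alpha
  res$mt_sig <- !is.na(res$p_mt) & res$p_mt <= thr
  res$ms_sig <- res$p_ms <= thr
  res$pattern <- paste0(ifelse(res$mt_sig, "sig", "ns"), "/",
                        ifelse(res$ms_sig, "sig", "ns"))
  res$pattern[!res$testable] <- "untestable"
  attr(res, "bonferroni_alpha") <- thr
  res
}

# Hudson-type FST between two site groups from a state matrix
pair_fst_seq <- function(st, pop, s1, s2) {
  st1 <- st[pop == s1, , drop = FALSE]
  st2 <- st[pop == s2, , drop = FALSE]
  kb <- seq_between_quants(st1, st2)
  if (kb <= 0) return(0)
  kw <- 0.5 * (seq_k_within(st1) + seq_k_within(st2))
  1 - kw / kb
}
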