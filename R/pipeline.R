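# End-to-end orchestration: synthetic study (or file inputs) through the
# mtDNA, microsatellite and clustering stages, with per-stage seeds
# derived from one global seed and a JSON master report.

#' Pipeline configuration
#'
#' @param outdir Output directory for the report bundle.
#' @param seed Global seed; each stage derives its own seed via
#'   [derive_seed()].
#' @param stages Stages to run, in dependency order, from
#'   `c("synth", "mtdna", "microsat", "cluster")`.
#' @param study A [study_config()] for the synth stage.
#' @param fasta,genotypes,sites Optional input paths used instead of the
#'   synth stage (all three required together; must exist).
#' @param n_perm,reps Permutation/replicate counts for the test-heavy
#'   stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L,
                            stages = c("synth", "mtdna", "microsat",
                                       "cluster"),
                            study = study_config(), fasta = NULL,
                            genotypes = NULL, sites = NULL,
                            n_perm = 199L, reps = 500L) {
  bad <- setdiff(stages, c("synth", "mtdna", "microsat", "cluster"))
  if (length(bad))
    stop_islandpop(paste("unknown stage(s):", paste(bad, collapse = ", ")),
                   "config_error")
  inputs <- c(fasta = fasta, genotypes = genotypes, sites = sites)
  for (p in inputs)
    if (!is.null(p) && !file.exists(p))
      stop_islandpop(paste("missing input file:", p), "config_error")
  structure(list(outdir = outdir, seed = seed, stages = stages,
                 study = study, fasta = fasta, genotypes = genotypes,
                 sites = sites, n_perm = n_perm, reps = reps),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order and writes a JSON
#' master report plus per-stage CSV/Newick artifacts under `outdir`.
#' A stage failure produces a partial bundle with a failure manifest
#' and the error is re-raised.
#'
#' @param cfg A [pipeline_config()].
#' @return The master report (list), invisibly; also written as
#'   `report.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = cfg$seed, stages = list())
  t0 <- Sys.time()
  state <- new.env()
  logfile <- file.path(cfg$outdir, "log.txt")
  cat(sprintf("islandpop %s | R %s | seed %d\n",
              as.character(utils::packageVersion("islandpop")),
              paste(R.version$major, R.version$minor, sep = "."),
              cfg$seed), file = logfile)

  run_stage <- function(name, fn) {
    st <- Sys.time()
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(res))
      jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      stop_islandpop(paste("stage", name, "failed:",
                           conditionMessage(res)), "stage_error")
    }
    res$status <- "ok"
    report$stages[[name]] <<- res
    cat(sprintf("stage %s: ok (%.2fs, seed %d)\n", name,
                as.numeric(difftime(Sys.time(), st, units = "secs")),
                derive_seed(cfg$seed, name)),
        file = logfile, append = TRUE)
  }

  load_inputs <- function() {
    if (!is.null(cfg$fasta)) {
      state$sites <- read_sites(cfg$sites)
      state$genotypes <- read_genotypes(cfg$genotypes, state$sites)
      labels <- setNames(state$genotypes$meta$site,
                         state$genotypes$meta$id)
      state$alignment <- read_alignment(cfg$fasta, labels)
    }
  }

  if ("synth" %in% cfg$stages) {
    run_stage("synth", function() {
      study <- generate_study(cfg$study, derive_seed(cfg$seed, "synth"))
      write_study(study, file.path(cfg$outdir, "synth"))
      state$alignment <- study$alignment
      state$genotypes <- study$genotypes
      state$sites <- study$sites
      state$truth <- study$truth
      list(n_individuals = nrow(study$genotypes$a1),
           n_sequenced = length(study$alignment$ids))
    })
  } else load_inputs()

  if ("mtdna" %in% cfg$stages) {
    run_stage("mtdna", function() {
      a <- state$alignment
      dv <- seq_diversity(a)
      mm <- mismatch_analysis(a)
      nt <- if (dv$S > 0)
        neutrality_tests(a, reps = cfg$reps,
                         seed = derive_seed(cfg$seed, "mtdna")) else NULL
      haps <- collapse_haplotypes(a)
      net <- if (length(haps$haplotypes) >= 2) median_joining(haps) else
        NULL
      if (!is.null(net))
        write_network_edgelist(net, file.path(cfg$outdir, "network.tsv"),
                               file.path(cfg$outdir, "network_nodes.csv"))
      list(S = dv$S, PI = dv$PI, pi = dv$pi, Hd = dv$Hd,
           n_haplotypes = length(haps$haplotypes),
           raggedness = mm$raggedness_r, SSD = mm$SSD,
           D_star = if (!is.null(nt)) nt$D_star else NA,
           F_star = if (!is.null(nt)) nt$F_star else NA,
           R2 = if (!is.null(nt)) nt$R2 else NA)
    })
  }

  if ("microsat" %in% cfg$stages) {
    run_stage("microsat", function() {
      g <- state$genotypes
      seed <- derive_seed(cfg$seed, "microsat")
      dv <- nei_diversity(g, "region")
      fs <- wc_fstats(g, "region", n_boot = 200, seed = seed)
      main_sites <- names(which(table(g$meta$site) >= 14))
      sel <- g$meta$site %in% main_sites
      g9 <- ep_genotypes(g$meta[sel, ], g$a1[sel, , drop = FALSE],
                         g$a2[sel, , drop = FALSE], g$loci)
      pw <- pairwise_fst_test(g9, "site", n_perm = cfg$n_perm,
                              seed = seed)
      tr <- distance_tree(pmax(pw$fst, 0))
      writeLines(tr$newick, file.path(cfg$outdir, "nj_tree.nwk"))
      write.csv(pw$fst, file.path(cfg$outdir, "pairwise_fst.csv"))
      write.csv(pw$p, file.path(cfg$outdir, "pairwise_fst_p.csv"))
      list(Ho = dv$overall$value[1], Hs = dv$overall$value[2],
           Ht = dv$overall$value[3],
           FIS = unname(fs$overall["FIS"]),
           FST = unname(fs$overall["FST"]),
           FIT = unname(fs$overall["FIT"]),
           n_significant_pairs = sum(pw$significant, na.rm = TRUE))
    })
  }

  if ("cluster" %in% cfg$stages) {
    run_stage("cluster", function() {
      g <- state$genotypes
      seed <- derive_seed(cfg$seed, "cluster")
      fc <- find_clusters(g, 1:6, seed = seed)
      dp <- dapc_fit(g, "region", n_pc = 10)
      write.csv(data.frame(id = g$meta$id, dp$coords),
                file.path(cfg$outdir, "dapc_coords.csv"),
                row.names = FALSE)
      list(BIC = as.list(fc$BIC), elbow_k = fc$elbow_k,
           dapc_reassignment = dp$reassignment)
    })
  }

  cat(sprintf("total: %.2fs\n",
              as.numeric(difftime(Sys.time(), t0, units = "secs"))),
      file = logfile, append = TRUE)
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
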