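# YAML/JSON scenario configuration: a portable declaration of
# scenarios, priors and marker configuration for the ABC engine.

#' Read a scenario/prior/marker configuration file
#'
#' The file (YAML or JSON) has three top-level blocks. `scenarios`
#' maps scenario ids to `pops`, `Ne` (number or parameter name per
#' population), `events` (list of `{type: merge|size|admix, time, ...}`
#' entries) and optional `conditions`. `priors` maps parameter names to
#' `{dist: unif|logunif|norm, ...}`. `config` declares the marker:
#' `marker: seq` with `samples`, `length`, `mu`, and optional HKY model
#' fields, or `marker: msat` with `samples`, `n_loci`, `motif`, `P`,
#' `mu`. An example lives at
#' `system.file("extdata", "composite_model.yaml", package = "islandpop")`.
#'
#' @param path Path to a YAML (or JSON) configuration file.
#' @return A list with `scenarios` (named [scenario()] list), `priors`
#'   and `config` ([sim_config_seq()] / [sim_config_msat()]).
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path))
    stop_islandpop(paste("no such file:", path), "config_error")
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  if (is.null(raw$scenarios) || is.null(raw$priors))
    stop_islandpop("config needs 'scenarios' and 'priors' blocks",
                   "config_error")
  scenarios <- lapply(names(raw$scenarios), function(nm) {
    sc <- raw$scenarios[[nm]]
    events <- lapply(sc$events %||% list(), function(e) {
      switch(e$type,
             merge = event_merge(e$time, e$from, e$to),
             size = event_size(e$time, e$pop, e$Ne),
             admix = event_admix(e$time, e$pop, unlist(e$donors),
                                 e$prop),
             stop_islandpop(paste("unknown event type:", e$type),
                            "config_error"))
    })
    scenario(nm, unlist(sc$pops), sc$Ne, events,
             conditions = unlist(sc$conditions %||% character()))
  })
  names(scenarios) <- names(raw$scenarios)
  priors <- lapply(raw$priors, function(p) {
    switch(p$dist,
           unif = prior_unif(p$min, p$max),
           logunif = prior_logunif(p$min, p$max),
           norm = prior_norm(p$mean, p$sd),
           stop_islandpop(paste("unknown prior:", p$dist),
                          "config_error"))
  })
  config <- NULL
  if (!is.null(raw$config)) {
    cc <- raw$config
    samples <- unlist(cc$samples)
    config <- if (identical(cc$marker, "msat"))
      sim_config_msat(samples, n_loci = cc$n_loci %||% 8L,
                      motif = unlist(cc$motif %||% 4L),
                      P = cc$P %||% 0.22, mu = cc$mu %||% 5e-4)
    else
      sim_config_seq(samples, length = cc$length %||% 491L,
                     model = subst_model(
                       "HKY",
                       gamma_shape = cc$gamma_shape %||% 0.78,
                       prop_invariant = cc$prop_invariant %||% 0.61,
                       kappa = cc$kappa %||% 4),
                     mu = cc$mu %||% 1e-6)
  }
  list(scenarios = scenarios, priors = priors, config = config)
}
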