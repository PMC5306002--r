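# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible per-stage seed from a global seed
#'
#' Stages of the pipeline must be independently reproducible: each stage
#' draws its own seed deterministically from the global seed and the stage
#' name, so inserting or removing one stage never perturbs another.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # small string hash (djb2) folded with the seed; kept below 2^31
  h <- 5381
  for (ch in utf8ToInt(stage)) h <- (h * 33 + ch) %% 2147483647
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483647)
}

# harmonic numbers a_n = sum_{i=1}^{n} 1/i (used by Watterson/Fu & Li)
harmonic <- function(n) if (n < 1) 0 else sum(1 / seq_len(n))
harmonic2 <- function(n) if (n < 1) 0 else sum(1 / seq_len(n)^2)

# weighted quantiles with linear interpolation on the weighted cdf
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- (cumsum(w) - w / 2) / sum(w)
  vapply(probs, function(p) {
    if (p <= cw[1]) return(x[1])
    if (p >= cw[length(cw)]) return(x[length(x)])
    i <- findInterval(p, cw)
    x[i] + (x[i + 1] - x[i]) * (p - cw[i]) / (cw[i + 1] - cw[i])
  }, numeric(1))
}

stop_islandpop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "islandpop_error")))
}
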