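# Median-joining haplotype networks (Bandelt, Forster & Roehl 1999) and
# outgroup-based identification of the ancestral haplotype.

hamming <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])

# pairwise Hamming distances between the rows of a character matrix
hamming_rows <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n)
  if (n > 1)
    for (i in seq_len(n - 1)) {
      rest <- m[(i + 1):n, , drop = FALSE]
      di <- as.integer(rowSums(rest != matrix(m[i, ], nrow(rest),
                                              ncol(m), byrow = TRUE)))
      d[i, (i + 1):n] <- di
      d[(i + 1):n, i] <- di
    }
  d
}

hamming_matrix <- function(seqs) {
  hamming_rows(do.call(rbind, strsplit(seqs, "", fixed = TRUE)))
}

# minimum-spanning-network edges: union over all minimum spanning trees,
# with tolerance epsilon on the connection level (Kruskal by levels).
msn_edges <- function(d, epsilon = 0) {
  n <- nrow(d)
  if (n == 1) return(matrix(numeric(0), 0, 3,
                            dimnames = list(NULL, c("i", "j", "w"))))
  # connection level c(u,v): minimax path weight under ascending merges
  comp <- seq_len(n)
  lev <- matrix(Inf, n, n)
  for (w in sort(unique(d[upper.tri(d)]))) {
    at <- which(d == w & upper.tri(d), arr.ind = TRUE)
    # record connection level for pairs joined at this stage
    newcomp <- comp
    for (r in seq_len(nrow(at))) {
      ci <- newcomp[at[r, 1]]; cj <- newcomp[at[r, 2]]
      if (ci != cj) newcomp[newcomp == cj] <- ci
    }
    for (u in seq_len(n - 1)) for (v in (u + 1):n)
      if (comp[u] != comp[v] && newcomp[u] == newcomp[v])
        lev[u, v] <- lev[v, u] <- w
    comp <- newcomp
  }
  keep <- which(upper.tri(d) & d <= lev + epsilon & d > 0, arr.ind = TRUE)
  cbind(i = keep[, 1], j = keep[, 2], w = d[keep])
}

# total length of a minimum spanning tree (Prim)
mst_length <- function(d) {
  n <- nrow(d)
  if (n <= 1) return(0)
  intree <- c(TRUE, rep(FALSE, n - 1))
  mind <- d[1, ]
  tot <- 0
  for (k in seq_len(n - 1)) {
    cand <- which(!intree)
    nxt <- cand[which.min(mind[cand])]
    tot <- tot + mind[nxt]
    intree[nxt] <- TRUE
    mind <- pmin(mind, d[nxt, ])
  }
  tot
}

# majority-state consensus of three sequences (ties keep the first's
# state); operates on character vectors
median_rows <- function(a, b, c) {
  out <- a
  bc <- b == c
  out[bc] <- b[bc]            # b agrees with c (covers abc-equal too)
  out
}

median_vector <- function(x, y, z) {
  paste(median_rows(strsplit(x, "")[[1]], strsplit(y, "")[[1]],
                    strsplit(z, "")[[1]]), collapse = "")
}

#' Median-joining haplotype network
#'
#' Builds the median-joining network of Bandelt et al. on the variable
#' sites of a haplotype set: the minimum-spanning network (union of all
#' minimum spanning trees, within tolerance `epsilon`) is iteratively
#' augmented with consensus (majority-state) median vectors of node
#' triplets whenever their addition strictly reduces the total minimum
#' spanning tree length; obsolete median vectors are pruned.
#'
#' @param h An [ep_haplotypes()] with at least 2 haplotypes.
#' @param epsilon Non-negative tolerance on the connection level
#'   (default 0, the usual program default).
#' @param max_median_rounds Safety cap on median-addition iterations.
#' @return A list of class `haplo_network`: `nodes` (data frame with
#'   `id`, `seq` over variable sites, `observed`, `freq` and per-region
#'   counts), `edges` (data frame `from`, `to`, `weight` in mutations),
#'   `variable_sites` (indices into the original alignment), and
#'   `total_length`.
#' @export
median_joining <- function(h, epsilon = 0, max_median_rounds = 50L) {
  stopifnot(inherits(h, "ep_haplotypes"))
  if (length(h$haplotypes) < 2)
    stop_islandpop("need >= 2 haplotypes", "domain_error")
  m <- do.call(rbind, strsplit(h$haplotypes, "", fixed = TRUE))
  varsites <- which(apply(m, 2, function(col) length(unique(col)) > 1))
  cond <- if (length(varsites))
    apply(m[, varsites, drop = FALSE], 1, paste, collapse = "")
  else rep("", nrow(m))
  M <- m[, varsites, drop = FALSE]
  observed <- rep(TRUE, nrow(M))
  # iterate: add the best cost-reducing median vector of a triplet that
  # shares a hub node in the current minimum-spanning network
  d <- hamming_rows(M)
  for (round in seq_len(max_median_rounds)) {
    n <- nrow(M)
    if (n < 3 || length(varsites) == 0) break
    base_cost <- mst_length(d)
    edges <- msn_edges(d, epsilon)
    adj <- vector("list", n)
    for (e in seq_len(nrow(edges))) {
      adj[[edges[e, 1]]] <- c(adj[[edges[e, 1]]], edges[e, 2])
      adj[[edges[e, 2]]] <- c(adj[[edges[e, 2]]], edges[e, 1])
    }
    best <- NULL; best_cost <- base_cost
    tried <- character(0)
    keys <- apply(M, 1, paste, collapse = "")
    for (v in seq_len(n)) {
      nb <- adj[[v]]
      if (length(nb) < 2) next
      prs <- combn(length(nb), 2)
      for (ci in seq_len(ncol(prs))) {
        u <- nb[prs[1, ci]]; w <- nb[prs[2, ci]]
        med <- median_rows(M[v, ], M[u, ], M[w, ])
        key <- paste(med, collapse = "")
        if (key %in% keys || key %in% tried) next
        tried <- c(tried, key)
        dm <- as.integer(rowSums(M != matrix(med, n, ncol(M),
                                             byrow = TRUE)))
        d2 <- rbind(cbind(d, dm), c(dm, 0L))
        cost <- mst_length(d2)
        if (cost < best_cost - 1e-9) {
          best_cost <- cost; best <- list(med = med, dm = dm)
        }
      }
    }
    if (is.null(best)) break
    M <- rbind(M, best$med)
    d <- rbind(cbind(d, best$dm), c(best$dm, 0L))
    observed <- c(observed, FALSE)
  }
  # prune obsolete median vectors (removal leaves MST length unchanged)
  repeat {
    cost <- mst_length(d)
    drop_idx <- NA
    for (i in which(!observed)) {
      if (mst_length(d[-i, -i, drop = FALSE]) <= cost + 1e-9) {
        drop_idx <- i; break
      }
    }
    if (is.na(drop_idx)) break
    M <- M[-drop_idx, , drop = FALSE]
    d <- d[-drop_idx, -drop_idx, drop = FALSE]
    observed <- observed[-drop_idx]
  }
  seqs <- apply(M, 1, paste, collapse = "")
  if (length(varsites) == 0) seqs <- cond
  edges <- msn_edges(d, epsilon)
  ids <- character(length(seqs))
  ids[observed] <- h$hap_ids[match(seqs[observed], cond)]
  ids[!observed] <- paste0("mv", seq_len(sum(!observed)))
  freq <- integer(length(seqs))
  freq[observed] <- rowSums(h$counts)[match(seqs[observed], cond)]
  nodes <- data.frame(id = ids, seq = seqs, observed = observed,
                      freq = freq, stringsAsFactors = FALSE)
  region_counts <- matrix(0L, length(seqs), ncol(h$counts),
                          dimnames = list(NULL, colnames(h$counts)))
  region_counts[observed, ] <- h$counts[match(seqs[observed], cond), ,
                                        drop = FALSE]
  nodes <- cbind(nodes, as.data.frame(region_counts))
  edges_df <- data.frame(from = ids[edges[, "i"]], to = ids[edges[, "j"]],
                         weight = as.integer(edges[, "w"]),
                         stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges_df,
                 variable_sites = varsites, total_length = mst_length(d),
                 full_haplotypes = h$haplotypes, epsilon = epsilon),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("<haplo_network> ", nrow(x$nodes), " nodes (",
      sum(!x$nodes$observed), " median vectors), ", nrow(x$edges),
      " edges, total length ", x$total_length, "\n", sep = "")
  invisible(x)
}

#' Identify the likely ancestral (root) haplotype via an outgroup
#'
#' The observed haplotype minimizing the Hamming distance to the
#' outgroup sequence is reported as ancestral; ties are broken by higher
#' frequency, then by higher node degree in the network.
#'
#' @param net A [median_joining()] network.
#' @param outgroup Outgroup sequence aligned to the original haplotypes
#'   (full length).
#' @return A list with `hap_id`, `distance` (mutations to the outgroup
#'   over usable sites) and the per-haplotype distance table.
#' @export
ancestral_haplotype <- function(net, outgroup) {
  haps <- net$full_haplotypes
  og <- toupper(outgroup)
  if (nchar(og) != nchar(haps[1]))
    stop_islandpop("outgroup not alignable to haplotypes", "domain_error")
  ogv <- strsplit(og, "")[[1]]
  usable <- ogv %in% c("A", "C", "G", "T")
  dists <- vapply(haps, function(hp) {
    hv <- strsplit(hp, "")[[1]]
    ok <- usable & hv %in% c("A", "C", "G", "T")
    sum(hv[ok] != ogv[ok])
  }, numeric(1))
  obs <- net$nodes[net$nodes$observed, ]
  deg <- table(factor(c(net$edges$from, net$edges$to),
                      levels = net$nodes$id))
  ord <- order(dists[match(obs$id, paste0("H", seq_along(haps)))],
               -obs$freq, -as.integer(deg[obs$id]))
  best <- obs$id[ord[1]]
  list(hap_id = best,
       distance = unname(dists[as.integer(sub("H", "", best))]),
       distances = setNames(unname(dists), paste0("H", seq_along(haps))))
}

#' Write a haplotype network as a tab-separated edge list
#'
#' Lines of `node1<TAB>node2<TAB>mutations`; the node table (frequency
#' and region composition) is written alongside as CSV when `node_path`
#' is given.
#'
#' @param net A `haplo_network`.
#' @param path Edge-list output path.
#' @param node_path Optional node-table CSV path.
#' @return `path`, invisibly.
#' @export
write_network_edgelist <- function(net, path, node_path = NULL) {
  writeLines(paste(net$edges$from, net$edges$to, net$edges$weight,
                   sep = "\t"), path)
  if (!is.null(node_path))
    write.csv(net$nodes, node_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a haplotype network as GraphML
#'
#' @param net A `haplo_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="freq" for="node" attr.name="freq" attr.type="int"/>',
    '  <key id="observed" for="node" attr.name="observed" attr.type="boolean"/>',
    '  <key id="w" for="edge" attr.name="mutations" attr.type="int"/>',
    '  <graph edgedefault="undirected">',
    vapply(seq_len(nrow(net$nodes)), function(i) paste0(
      '    <node id="', esc(net$nodes$id[i]), '">',
      '<data key="freq">', net$nodes$freq[i], '</data>',
      '<data key="observed">', tolower(net$nodes$observed[i]), '</data>',
      '</node>'), character(1)),
    vapply(seq_len(nrow(net$edges)), function(i) paste0(
      '    <edge source="', esc(net$edges$from[i]), '" target="',
      esc(net$edges$to[i]), '"><data key="w">', net$edges$weight[i],
      '</data></edge>'), character(1)),
    '  </graph>', '</graphml>')
  writeLines(lines, path)
  invisible(path)
}
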