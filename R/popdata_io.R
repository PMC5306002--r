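# Shared data model and readers/writers for the external formats:
# FASTA alignments, diploid genotype CSV tables, STRUCTURE export and the
# site metadata table.

#' Construct an aligned set of haploid sequences
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param seqs Character vector of equal-length sequences over
#'   `A,C,G,T,-,N` (case-insensitive; stored uppercased).
#' @param labels Optional named character vector mapping ids to a
#'   site/region code.
#' @return An object of class `ep_alignment` with fields `ids`, `seqs`,
#'   `length` (sites) and `labels`.
#' @export
ep_alignment <- function(ids, seqs, labels = NULL) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    stop_islandpop("ids and seqs differ in length", "format_error")
  if (length(seqs) == 0L)
    stop_islandpop("empty alignment", "format_error")
  if (anyDuplicated(ids))
    stop_islandpop("duplicated sequence ids", "format_error")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop_islandpop("ragged alignment: sequences differ in length",
                   "length_mismatch_error")
  if (lens[1] == 0L)
    stop_islandpop("zero-length sequences", "format_error")
  if (!is.null(labels)) labels <- labels[ids]
  structure(list(ids = ids, seqs = seqs, length = lens[1], labels = labels),
            class = "ep_alignment")
}

#' @export
print.ep_alignment <- function(x, ...) {
  cat("<ep_alignment> ", length(x$ids), " sequences x ", x$length, " bp\n",
      sep = "")
  invisible(x)
}

# character matrix view (n x sites), rownames = ids
aln_matrix <- function(a) {
  m <- do.call(rbind, strsplit(a$seqs, "", fixed = TRUE))
  rownames(m) <- a$ids
  m
}

# columns usable for site-based statistics: every sequence has A/C/G/T
# (complete deletion of gap/ambiguity columns)
usable_sites <- function(m) {
  ok <- colSums(matrix(m %in% c("A", "C", "G", "T"), nrow(m))) == nrow(m)
  which(ok)
}

#' Read an aligned FASTA file
#'
#' Sequences are uppercased; identifiers are taken from the FASTA headers
#' (first whitespace-delimited token). Ragged inputs raise a
#' length-mismatch error; empty files a format error.
#'
#' @param path Path to a FASTA file.
#' @param labels Optional named character vector of id -> group labels.
#' @return An [ep_alignment()].
#' @export
read_alignment <- function(path, labels = NULL) {
  if (!file.exists(path))
    stop_islandpop(paste("no such file:", path), "format_error")
  dna <- tryCatch(
    suppressWarnings(ape::read.dna(path, format = "fasta",
                                   as.character = TRUE,
                                   as.matrix = FALSE)),
    error = function(e) stop_islandpop(paste("FASTA parse failure:",
                                             conditionMessage(e)),
                                       "format_error"))
  if (length(dna) == 0L)
    stop_islandpop("empty FASTA file", "format_error")
  ids <- sub("\\s.*$", "", names(dna))
  seqs <- vapply(dna, function(s) paste(s, collapse = ""), character(1))
  if (any(nchar(seqs) == 0L))
    stop_islandpop("empty sequence record", "format_error")
  ep_alignment(ids, seqs, labels)
}

#' Write an alignment as FASTA
#'
#' @param a An [ep_alignment()].
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(a, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(a$ids)) {
    writeLines(paste0(">", a$ids[i]), con)
    s <- a$seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Collapse aligned sequences to frequency-weighted haplotypes
#'
#' Distinct sequences become haplotypes, ordered by first occurrence.
#' When the alignment carries labels, per-group counts are tabulated.
#'
#' @param a An [ep_alignment()].
#' @return An object of class `ep_haplotypes`: `haplotypes` (sequences),
#'   `hap_ids`, `counts` (matrix haplotype x group; single column `all`
#'   when unlabelled), `n` total sequences, and `assignment` mapping each
#'   input sequence to its haplotype index.
#' @export
collapse_haplotypes <- function(a) {
  stopifnot(inherits(a, "ep_alignment"))
  idx <- match(a$seqs, unique(a$seqs))
  haps <- unique(a$seqs)
  groups <- if (is.null(a$labels)) rep("all", length(a$seqs)) else
    as.character(a$labels)
  counts <- table(factor(idx, levels = seq_along(haps)), groups)
  counts <- matrix(as.integer(counts), nrow = length(haps),
                   dimnames = list(NULL, colnames(counts)))
  structure(list(
    haplotypes = haps,
    hap_ids = paste0("H", seq_along(haps)),
    counts = counts,
    n = length(a$seqs),
    assignment = idx,
    length = a$length
  ), class = "ep_haplotypes")
}

#' @export
print.ep_haplotypes <- function(x, ...) {
  cat("<ep_haplotypes> ", length(x$haplotypes), " haplotypes from ", x$n,
      " sequences\n", sep = "")
  invisible(x)
}

#' Construct a diploid microsatellite genotype matrix
#'
#' @param meta Data frame with columns `id`, `site`, `region`, `sex`,
#'   `stage` (one row per individual).
#' @param a1,a2 Integer matrices (individuals x loci) of allele sizes in
#'   bp; a call is either complete (both alleles) or wholly missing
#'   (both `NA`).
#' @param loci Character vector of locus names.
#' @return An object of class `ep_genotypes`.
#' @export
ep_genotypes <- function(meta, a1, a2, loci = colnames(a1)) {
  stopifnot(nrow(meta) == nrow(a1), all(dim(a1) == dim(a2)))
  half <- xor(is.na(a1), is.na(a2))
  if (any(half))
    stop_islandpop("half-missing genotype call", "parse_error")
  if (any(a1[!is.na(a1)] <= 0) || any(a2[!is.na(a2)] <= 0))
    stop_islandpop("allele sizes must be positive integers", "parse_error")
  dimnames(a1) <- dimnames(a2) <- list(meta$id, loci)
  structure(list(meta = meta, a1 = a1, a2 = a2, loci = loci),
            class = "ep_genotypes")
}

#' @export
print.ep_genotypes <- function(x, ...) {
  cat("<ep_genotypes> ", nrow(x$a1), " individuals x ", ncol(x$a1),
      " loci; ", sum(is.na(x$a1)), " missing calls\n", sep = "")
  invisible(x)
}

#' Read a diploid genotype CSV table
#'
#' Expected header: `id,site,region,sex,stage` followed by one column per
#' locus holding `a1/a2` allele sizes in bp, with missing calls coded
#' `NA`. Individuals failing more than `max_missing` loci are dropped
#' with a message (retention mirrors typical amplification-failure
#' screens).
#'
#' @param path CSV path.
#' @param sites Optional site table ([read_sites()]); unknown site codes
#'   then raise a metadata error.
#' @param max_missing Maximum number of missing loci tolerated per
#'   individual (default 2).
#' @return An [ep_genotypes()] with attribute `completeness`, a data
#'   frame reporting complete/partial/dropped individuals.
#' @export
read_genotypes <- function(path, sites = NULL, max_missing = 2L) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "site", "region", "sex", "stage")
  if (!all(need %in% names(df)))
    stop_islandpop("genotype table must start with id,site,region,sex,stage",
                   "parse_error")
  loci <- setdiff(names(df), need)
  if (length(loci) == 0L)
    stop_islandpop("no locus columns", "parse_error")
  if (!is.null(sites)) {
    bad <- setdiff(unique(df$site), sites$code)
    if (length(bad))
      stop_islandpop(paste("unknown site code(s):",
                           paste(bad, collapse = ", ")), "metadata_error")
  }
  n <- nrow(df)
  a1 <- a2 <- matrix(NA_integer_, n, length(loci))
  for (j in seq_along(loci)) {
    cell <- trimws(as.character(df[[loci[j]]]))
    miss <- is.na(cell) | cell == "NA" | cell == ""
    parts <- strsplit(cell[!miss], "/", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop_islandpop(paste("locus", loci[j], "has a call without two alleles"),
                     "parse_error")
    a1[!miss, j] <- as.integer(vapply(parts, `[`, character(1), 1L))
    a2[!miss, j] <- as.integer(vapply(parts, `[`, character(1), 2L))
  }
  miss_per_ind <- rowSums(is.na(a1))
  keep <- miss_per_ind <= max_missing
  report <- data.frame(id = df$id, missing_loci = miss_per_ind,
                       status = ifelse(!keep, "dropped",
                                ifelse(miss_per_ind == 0, "complete",
                                       "partial")))
  if (any(!keep))
    message(sum(!keep), " individual(s) dropped (> ", max_missing,
            " failed loci)")
  g <- ep_genotypes(df[keep, need], a1[keep, , drop = FALSE],
                    a2[keep, , drop = FALSE], loci)
  attr(g, "completeness") <- report
  g
}

#' Write a genotype table as CSV
#'
#' Inverse of [read_genotypes()]: calls are written as `a1/a2`, missing
#' calls as `NA`.
#'
#' @param g An [ep_genotypes()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  df <- g$meta
  for (j in seq_along(g$loci)) {
    cell <- ifelse(is.na(g$a1[, j]), NA,
                   paste0(g$a1[, j], "/", g$a2[, j]))
    df[[g$loci[j]]] <- cell
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Export genotypes in STRUCTURE two-row format
#'
#' Two rows per individual, one column per locus, missing alleles coded
#' -9, with a numeric location column (site index).
#'
#' @param g An [ep_genotypes()].
#' @param path Optional output path; when `NULL` the lines are returned.
#' @return Character vector of file lines, invisibly when `path` given.
#' @export
export_structure_file <- function(g, path = NULL) {
  loc <- as.integer(factor(g$meta$site))
  lines <- character(2L * nrow(g$a1))
  for (i in seq_len(nrow(g$a1))) {
    r1 <- ifelse(is.na(g$a1[i, ]), -9L, g$a1[i, ])
    r2 <- ifelse(is.na(g$a2[i, ]), -9L, g$a2[i, ])
    lines[2 * i - 1] <- paste(c(g$meta$id[i], loc[i], r1), collapse = " ")
    lines[2 * i]     <- paste(c(g$meta$id[i], loc[i], r2), collapse = " ")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read a site metadata table
#'
#' CSV with columns `code,name,region,lat,lon,altitude,n_msat,n_mtdna`;
#' `region` must be one of North/Central/South and codes unique.
#'
#' @param path CSV path.
#' @return A data frame of class `ep_sites`.
#' @export
read_sites <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("code", "name", "region", "lat", "lon", "altitude",
            "n_msat", "n_mtdna")
  if (!all(need %in% names(df)))
    stop_islandpop("site table missing required columns", "parse_error")
  if (anyDuplicated(df$code))
    stop_islandpop("duplicate site codes", "metadata_error")
  if (any(!df$region %in% c("North", "Central", "South")))
    stop_islandpop("region must be North/Central/South", "metadata_error")
  class(df) <- c("ep_sites", "data.frame")
  df
}

#' Write a site metadata table
#' @param sites An `ep_sites` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  write.csv(as.data.frame(sites), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
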