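# Conserved gene-neighborhood comparison around focal loci: ordered
# neighborhoods, shared-ortholog counts, Jaccard, collinear runs, and an
# empirical permutation null.

#' Read a BED-like gene table
#'
#' Six-column tab-separated text: scaffold, start, end, gene_id, score
#' placeholder, strand. Coordinates are 0-based half-open.
#'
#' @param path input path.
#' @return Validated data frame with columns `scaffold`, `start`, `end`,
#'   `gene_id`, `score`, `strand`.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("scaffold", "start", "end",
                                        "gene_id", "score", "strand"),
                          stringsAsFactors = FALSE)
  validate_gene_table(df)
}

#' Validate a gene table
#'
#' @param df data frame with at least `scaffold`, `start`, `end`, `gene_id`,
#'   `strand`.
#' @return The validated data frame.
#' @export
validate_gene_table <- function(df) {
  stopifnot(all(c("scaffold", "start", "end", "gene_id", "strand")
                %in% names(df)))
  if (any(df$start >= df$end)) stop("gene table: start must be < end",
                                    call. = FALSE)
  if (anyDuplicated(df$gene_id)) stop("gene table: gene_id not unique",
                                      call. = FALSE)
  if (!all(df$strand %in% c("+", "-"))) {
    stop("gene table: strand must be + or -", call. = FALSE)
  }
  df
}

#' Read an ortholog-pair map
#'
#' Two-column tab-separated text (gene_id_A, gene_id_B). Pairs may be
#' many-to-many; duplicated pairs are dropped and the many-to-many condition
#' is flagged in the attribute `many_to_many`.
#'
#' @param path input path.
#' @return Data frame with columns `gene_a`, `gene_b`.
#' @export
read_orthology <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("gene_a", "gene_b"),
                          stringsAsFactors = FALSE)
  as_orthology(df)
}

#' @rdname read_orthology
#' @param df data frame with columns `gene_a`, `gene_b`.
#' @export
as_orthology <- function(df) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(df)))
  df <- df[!duplicated(df[c("gene_a", "gene_b")]), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "many_to_many") <-
    anyDuplicated(df$gene_a) > 0L || anyDuplicated(df$gene_b) > 0L
  df
}

#' Ordered gene neighborhood around a focal gene
#'
#' Up to `k` genes on each side of the focal gene on the same scaffold,
#' ordered by start coordinate (gene order, not bp distance, defines the
#' neighborhood). Truncation at scaffold ends is reported.
#'
#' @param table gene table (see [read_gene_table()]).
#' @param focal_gene focal gene id (must be present).
#' @param k flank size in genes (>= 0).
#' @return Data frame of neighbor genes (the focal gene excluded) with
#'   attributes `focal` and `truncated` (genes missing per side).
#' @export
neighborhood <- function(table, focal_gene, k = 10) {
  stopifnot(k >= 0)
  hit <- which(table$gene_id == focal_gene)
  if (length(hit) != 1L) stop("focal gene not found: ", focal_gene,
                              call. = FALSE)
  scf <- table$scaffold[hit]
  sub <- table[table$scaffold == scf, , drop = FALSE]
  sub <- sub[order(sub$start), , drop = FALSE]
  i <- which(sub$gene_id == focal_gene)
  left <- sub[seq_len(i - 1L), , drop = FALSE]
  right <- sub[seq_len(nrow(sub)) > i, , drop = FALSE]
  left <- utils::tail(left, k)
  right <- utils::head(right, k)
  nb <- rbind(left, right)
  rownames(nb) <- NULL
  attr(nb, "focal") <- focal_gene
  attr(nb, "truncated") <- c(left = k - nrow(left), right = k - nrow(right))
  nb
}

# Longest common subsequence length of gene-id vectors a and b under the
# match relation "is an ortholog pair".
.lcs_length <- function(a, b, pairs) {
  na <- length(a); nb <- length(b)
  if (!na || !nb) return(0L)
  key <- paste(pairs$gene_a, pairs$gene_b, sep = "\r")
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    for (j in seq_len(nb)) {
      if (paste(a[i], b[j], sep = "\r") %in% key) {
        cur[j + 1L] <- prev[j] + 1L
      } else {
        cur[j + 1L] <- max(prev[j + 1L], cur[j])
      }
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' Compare two gene neighborhoods
#'
#' Shared genes are counted with set semantics (a gene with several orthologs
#' in the other window still counts once). The collinearity statistic is the
#' longest common subsequence of ortholog-matched gene orders, taken over B
#' in forward and reversed orientation (strand/inversion agnostic).
#'
#' @param nbA,nbB neighborhoods from [neighborhood()].
#' @param orthology ortholog-pair data frame (`gene_a` from A's genome,
#'   `gene_b` from B's).
#' @return Object of class `neighborhood_comparison`: list with `shared_count`,
#'   `jaccard`, `max_collinear_run`, `n_a`, `n_b`.
#' @export
compare_neighborhoods <- function(nbA, nbB, orthology) {
  a <- nbA$gene_id; b <- nbB$gene_id
  orth <- orthology[orthology$gene_a %in% a & orthology$gene_b %in% b, ,
                    drop = FALSE]
  shared <- length(unique(orth$gene_a))
  denom <- length(a) + length(b) - shared
  jac <- if (denom > 0) shared / denom else 0
  run <- max(.lcs_length(a, b, orth), .lcs_length(a, rev(b), orth))
  out <- list(shared_count = shared, jaccard = jac,
              max_collinear_run = run,
              n_a = length(a), n_b = length(b))
  class(out) <- "neighborhood_comparison"
  out
}

#' @export
print.neighborhood_comparison <- function(x, ...) {
  cat(sprintf(
    "Neighborhood comparison: %d/%d vs %d genes shared (Jaccard %.3f), max collinear run %d\n",
    x$shared_count, x$n_a, x$n_b, x$jaccard, x$max_collinear_run))
  invisible(x)
}

#' Permutation null for shared-neighbor counts
#'
#' The observed `shared_count` around the focal pair is compared with a null
#' in which the B-side neighborhood is replaced by a random draw of the same
#' number of genes from table B. The empirical p-value uses the add-one rule
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param tableA,tableB gene tables.
#' @param orthology ortholog pairs (A ids in `gene_a`, B ids in `gene_b`).
#' @param focalA,focalB focal gene ids.
#' @param k neighborhood flank size.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed.
#' @return List with `observed` (a `neighborhood_comparison`), `p_value` and
#'   the integer vector `null_shared`.
#' @export
permutation_null <- function(tableA, tableB, orthology, focalA, focalB,
                             k = 10, n_perm = 999, seed = 1) {
  stopifnot(n_perm >= 99)
  nbA <- neighborhood(tableA, focalA, k)
  nbB <- neighborhood(tableB, focalB, k)
  obs <- compare_neighborhoods(nbA, nbB, orthology)
  pool <- setdiff(tableB$gene_id, focalB)
  size <- min(nrow(nbB), length(pool))
  a <- nbA$gene_id
  null_shared <- .with_seed(seed, vapply(seq_len(n_perm), function(i) {
    bset <- sample(pool, size)
    hit <- orthology[orthology$gene_a %in% a & orthology$gene_b %in% bset, ,
                     drop = FALSE]
    length(unique(hit$gene_a))
  }, integer(1L)))
  p <- (1 + sum(null_shared >= obs$shared_count)) / (1 + n_perm)
  list(observed = obs, p_value = p, null_shared = null_shared)
}
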