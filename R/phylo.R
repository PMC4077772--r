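# Distance-based phylogenetics: p / Poisson-corrected amino-acid distances,
# a deterministic Saitou-Nei neighbor-joining implementation, nonparametric
# bootstrap over alignment columns, and outgroup rooting. Trees are ape
# "phylo" objects throughout; Newick I/O goes through ape.

#' Read an amino-acid alignment from aligned FASTA
#'
#' @param path aligned FASTA file; rows must be equal length, gaps as `-`.
#' @return Named character vector of aligned rows (class `aa_alignment`).
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  aln <- toupper(as.character(set))
  as_alignment(aln)
}

#' Validate a named character vector as an alignment
#'
#' @param rows named character vector of equal-length gapped sequences.
#' @return The input, validated, with class `aa_alignment`.
#' @export
as_alignment <- function(rows) {
  if (length(rows) < 3L) stop("alignment needs >= 3 taxa", call. = FALSE)
  if (is.null(names(rows)) || anyDuplicated(names(rows))) {
    stop("alignment rows must carry unique taxon names", call. = FALSE)
  }
  if (length(unique(nchar(rows))) != 1L) {
    stop("alignment rows must be equal length", call. = FALSE)
  }
  class(rows) <- "aa_alignment"
  rows
}

.aln_matrix <- function(aln) {
  do.call(rbind, strsplit(unclass(aln), "", fixed = TRUE))
}

#' Pairwise amino-acid distances
#'
#' Proportion of differing residues (`model = "p"`) or its Poisson correction
#' `-log(1 - p)` (`model = "poisson"`). Gap handling: `pairwise` deletion
#' drops, per pair, the columns where either row has a gap; `complete`
#' deletion drops every column containing any gap.
#'
#' @param aln an alignment from [read_alignment()]/[as_alignment()].
#' @param model `"poisson"` (default) or `"p"`.
#' @param gap_mode `"pairwise"` (default) or `"complete"`.
#' @return Symmetric labeled distance matrix with zero diagonal.
#' @export
pairwise_distance <- function(aln, model = c("poisson", "p"),
                              gap_mode = c("pairwise", "complete")) {
  model <- match.arg(model)
  gap_mode <- match.arg(gap_mode)
  m <- .aln_matrix(aln)
  taxa <- names(aln)
  if (gap_mode == "complete") {
    keep <- colSums(m == "-") == 0L
    if (!any(keep)) stop("no gap-free columns under complete deletion",
                         call. = FALSE)
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) {
        stop("no comparable sites between ", taxa[i], " and ", taxa[j],
             call. = FALSE)
      }
      p <- mean(m[i, ok] != m[j, ok])
      if (model == "poisson") {
        if (p >= 1) {
          stop("undefined poisson distance (p = 1) between ", taxa[i],
               " and ", taxa[j], call. = FALSE)
        }
        d[i, j] <- d[j, i] <- -log(1 - p)
      } else {
        d[i, j] <- d[j, i] <- p
      }
    }
  }
  d
}

# Quote-free sanity check for labels that must survive a Newick round trip.
.check_labels <- function(labels) {
  bad <- grepl("[(),:;'\"\\s]", labels, perl = TRUE)
  if (any(bad)) {
    stop("labels not representable in Newick without quoting: ",
         paste(labels[bad], collapse = ", "), call. = FALSE)
  }
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q-criterion and branch-length
#' formulas. Ties in Q are broken deterministically by the lexicographically
#' smallest pair of cluster keys (a cluster's key is its smallest leaf
#' label). Negative branch-length estimates are clamped to zero with a
#' warning.
#'
#' @param dm symmetric distance matrix with labeled rows/columns and zero
#'   diagonal (>= 3 labels).
#' @param clamp_negative clamp negative branch lengths to 0 (default TRUE).
#' @return Unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dm, clamp_negative = TRUE) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) {
    stop("dm must be a square matrix", call. = FALSE)
  }
  if (max(abs(dm - t(dm))) > 1e-8) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  labels <- rownames(dm)
  if (is.null(labels)) stop("dm must have row/column labels", call. = FALSE)
  .check_labels(labels)
  n <- nrow(dm)
  if (n < 3L) stop("neighbor joining needs >= 3 taxa", call. = FALSE)
  had_negative <- FALSE
  clip <- function(x) {
    if (x < 0) {
      had_negative <<- TRUE
      if (clamp_negative) return(0)
    }
    x
  }
  fmt <- function(x) sprintf("%.10g", x)
  # active clusters: Newick fragment + sort key (smallest leaf label)
  node <- as.list(labels)
  key <- labels
  d <- dm
  while (length(node) > 3L) {
    r <- length(node)
    rs <- rowSums(d)
    best <- NULL
    for (i in seq_len(r - 1L)) {
      for (j in (i + 1L):r) {
        q <- (r - 2) * d[i, j] - rs[i] - rs[j]
        pair_key <- sort(c(key[i], key[j]))
        if (is.null(best) || q < best$q - 1e-12 ||
            (abs(q - best$q) <= 1e-12 &&
             (pair_key[1L] < best$key[1L] ||
              (pair_key[1L] == best$key[1L] && pair_key[2L] < best$key[2L])))) {
          best <- list(q = q, i = i, j = j, key = pair_key)
        }
      }
    }
    i <- best$i; j <- best$j
    li <- clip(d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2)))
    lj <- clip(d[i, j] - (d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))))
    merged <- paste0("(", node[[i]], ":", fmt(li), ",",
                     node[[j]], ":", fmt(lj), ")")
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    node <- c(node[keep], merged)
    key <- c(key[keep], min(best$key))
    rownames(d2) <- colnames(d2) <- NULL
    d <- d2
  }
  # final three-point join
  la <- clip((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  lb <- clip((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  lc <- clip((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  text <- paste0("(", node[[1L]], ":", fmt(la), ",",
                 node[[2L]], ":", fmt(lb), ",",
                 node[[3L]], ":", fmt(lc), ");")
  if (had_negative && clamp_negative) {
    warning("negative branch-length estimate(s) clamped to 0", call. = FALSE)
  }
  ape::read.tree(text = text)
}

#' Leaf bipartitions of a tree
#'
#' One canonical signature per internal edge: the side of the split not
#' containing the alphabetically first taxon, written as sorted labels joined
#' by `|`. Trivial splits (single leaves, full set) are excluded. Rooting
#' does not change the signatures.
#'
#' @param tree a `phylo` object.
#' @return Character vector of bipartition signatures.
#' @export
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1L]
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  sigs <- vapply(parts, function(idx) {
    side <- labs[idx]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > length(tips) - 2L) {
      return(NA_character_)
    }
    paste(sort(side), collapse = "|")
  }, character(1L))
  unique(sigs[!is.na(sigs)])
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Columns are resampled with replacement `n_reps` times; each replicate is
#' rebuilt with the same distance model, and an internal edge's support is
#' the percentage of replicates whose tree contains the same leaf
#' bipartition. Replicates with undefined distances (e.g. a Poisson p = 1)
#' are redrawn; redraws are counted and capped.
#'
#' @param aln an `aa_alignment`.
#' @param model,gap_mode passed to [pairwise_distance()].
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed RNG seed (replicate r draws from its own derived substream).
#' @param max_redraw cap on total redraws before erroring with advice.
#' @return The NJ tree for the full alignment with `node.label` carrying
#'   support percentages, plus attributes `bipartition_support` (data frame
#'   `bipartition`, `support`) and `n_redrawn`.
#' @export
bootstrap_support <- function(aln, model = "poisson", gap_mode = "pairwise",
                              n_reps = 1000, seed = 1,
                              max_redraw = 10 * n_reps) {
  stopifnot(n_reps >= 1)
  main <- neighbor_joining(pairwise_distance(aln, model, gap_mode))
  main_sig <- tree_bipartitions(main)
  m <- .aln_matrix(aln)
  ncol_aln <- ncol(m)
  taxa <- names(aln)
  counts <- setNames(numeric(length(main_sig)), main_sig)
  n_redrawn <- 0L
  rep_seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1L, n_reps))
  for (r in seq_len(n_reps)) {
    sigs <- .with_seed(rep_seeds[r], {
      repeat {
        cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
        rows <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
        rep_aln <- as_alignment(setNames(rows, taxa))
        dm <- tryCatch(pairwise_distance(rep_aln, model, gap_mode),
                       error = function(e) NULL)
        if (!is.null(dm)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > max_redraw) {
          stop("bootstrap redraw cap exceeded: distances repeatedly ",
               "undefined; consider model = 'p' or more alignment columns",
               call. = FALSE)
        }
      }
      suppressWarnings(tree_bipartitions(neighbor_joining(dm)))
    })
    hit <- main_sig %in% sigs
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / n_reps
  main <- .attach_support(main, support)
  attr(main, "bipartition_support") <- data.frame(
    bipartition = names(support), support = unname(support),
    stringsAsFactors = FALSE)
  attr(main, "n_redrawn") <- n_redrawn
  main
}

# Write per-bipartition supports onto node labels (internal nodes whose
# clade corresponds to a supported split; others stay blank).
.attach_support <- function(tree, support) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1L]
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  node_lab <- character(tree$Nnode)
  for (k in seq_along(parts)) {
    side <- labs[parts[[k]]]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > length(tips) - 2L) next
    sig <- paste(sort(side), collapse = "|")
    if (sig %in% names(support)) {
      node_lab[k] <- sprintf("%g", support[[sig]])
    }
  }
  tree$node.label <- node_lab
  tree
}

#' Root a tree on an outgroup
#'
#' Places the root at the midpoint of the outgroup's pendant edge. Bootstrap
#' supports are bipartition properties and are carried over unchanged (the
#' `bipartition_support` attribute is preserved).
#'
#' @param tree a `phylo` object.
#' @param outgroup_label tip label to root on.
#' @return Rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup_label) {
  tip <- which(tree$tip.label == outgroup_label)
  if (length(tip) != 1L) {
    stop("outgroup label not found in tree: ", outgroup_label, call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    rooted <- ape::root(tree, outgroup = outgroup_label, resolve.root = TRUE)
  } else {
    pend <- which(tree$edge[, 2L] == tip)
    rooted <- phytools::reroot(tree, tip,
                               position = tree$edge.length[pend] / 2)
  }
  attr(rooted, "bipartition_support") <- attr(tree, "bipartition_support")
  rooted
}

#' Read a Newick tree
#'
#' @param text Newick string (used when `path` is `NULL`).
#' @param path optional file to read from instead.
#' @return A `phylo` tree; branch lengths and internal node (support) labels
#'   are preserved, and absent lengths stay absent rather than becoming 0.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  src <- if (!is.null(path)) paste(readLines(path, warn = FALSE),
                                   collapse = "") else text
  if (is.null(src)) stop("provide text or path", call. = FALSE)
  depth <- 0L
  chars <- strsplit(src, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop("Newick parse error: unbalanced ')' at character ", i,
           call. = FALSE)
    }
  }
  if (depth != 0L) {
    stop("Newick parse error: ", depth, " unclosed '(' at end of input",
         call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(text = src), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree)) stop("Newick parse error in: ", src, call. = FALSE)
  tree
}

#' Write a tree as Newick
#'
#' @param tree a `phylo` object.
#' @param path optional output file; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  text <- ape::write.tree(tree)
  if (is.null(path)) return(text)
  writeLines(text, path)
  invisible(text)
}
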