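# Independent oracles used to compute expected values; these deliberately
# avoid the package's own code paths.

# --- peptide masses from elemental compositions -----------------------------
# monoisotopic atom masses
.ATOM <- c(H = 1.00782503207, C = 12, N = 14.0030740048,
           O = 15.9949146196, S = 31.97207100)

# residue formulas (amino acid minus water), counts of C,H,N,O,S
.RESIDUE_FORMULA <- list(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0)
)

oracle_peptide_mass <- function(sequence, amidated = FALSE) {
  total <- 0
  for (ch in strsplit(sequence, "")[[1]]) {
    f <- .RESIDUE_FORMULA[[ch]]
    total <- total + f[1] * .ATOM["C"] + f[2] * .ATOM["H"] +
      f[3] * .ATOM["N"] + f[4] * .ATOM["O"] + f[5] * .ATOM["S"]
  }
  total <- total + 2 * .ATOM["H"] + .ATOM["O"]            # water
  if (amidated) total <- total + .ATOM["N"] + .ATOM["H"] - .ATOM["O"]
  unname(total)
}

oracle_proton <- 1.00727646677

random_peptide <- function(len) {
  paste(sample(names(.RESIDUE_FORMULA), len, replace = TRUE), collapse = "")
}

# --- exhaustive-scan signal peptide oracle ----------------------------------
# Direct re-derivation of the rule: most hydrophobic window in the first 40
# residues (N-terminal tie-break), then the (-3,-1)-compatible cut closest to
# the end of that core, at most 8 residues past it.
oracle_signal_scan <- function(protein, window = 7, threshold = 1.6,
                               search_limit = 40, max_offset = 8) {
  kd <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
          I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
          R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
  ch <- strsplit(protein, "")[[1]]
  n <- length(ch)
  if (n < 15) return(NA_integer_)
  lim <- min(search_limit, n)
  if (lim < window) return(NA_integer_)
  best <- -Inf; best_s <- NA
  for (s in 1:(lim - window + 1)) {
    sc <- 0
    for (t in s:(s + window - 1)) sc <- sc + kd[[ch[t]]]
    sc <- sc / window
    if (sc > best + 1e-12) { best <- sc; best_s <- s }
  }
  if (best < threshold) return(NA_integer_)
  core_end <- best_s + window - 1
  for (p in core_end:min(core_end + max_offset, n - 1)) {
    if (p < 3) next
    if (ch[p] %in% c("A", "G", "S", "C", "T", "Q") &&
        ch[p - 2] %in% c("A", "V", "S", "C", "T", "G", "I", "L")) {
      return(as.integer(p))
    }
  }
  NA_integer_
}

# --- brute-force LCS --------------------------------------------------------
oracle_lcs <- function(a, b, is_match) {
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) return(0L)
  dp <- matrix(0L, na + 1, nb + 1)
  for (i in 1:na) {
    for (j in 1:nb) {
      dp[i + 1, j + 1] <- if (is_match(a[i], b[j])) {
        dp[i, j] + 1L
      } else {
        max(dp[i, j + 1], dp[i + 1, j])
      }
    }
  }
  dp[na + 1, nb + 1]
}

# --- exhaustive topology / least-squares oracle -----------------------------
# Enumerate all unrooted binary topologies on the given leaf labels as edge
# matrices (leaves 1..n, internal nodes > n).
enumerate_topologies <- function(n) {
  stopifnot(n >= 3)
  base <- list(list(edges = rbind(c(n + 1, 1), c(n + 1, 2), c(n + 1, 3)),
                    next_node = n + 2))
  if (n == 3) return(lapply(base, `[[`, "edges"))
  cur <- base
  for (leaf in 4:n) {
    nxt <- list()
    for (topo in cur) {
      for (e in seq_len(nrow(topo$edges))) {
        m <- topo$next_node
        ed <- topo$edges
        a <- ed[e, 1]; b <- ed[e, 2]
        ed <- ed[-e, , drop = FALSE]
        ed <- rbind(ed, c(a, m), c(m, b), c(m, leaf))
        nxt[[length(nxt) + 1]] <- list(edges = ed, next_node = m + 1)
      }
    }
    cur <- nxt
  }
  lapply(cur, `[[`, "edges")
}

.tree_path <- function(edges, from, to) {
  # BFS over the edge list; returns indices of edges on the path
  nodes <- unique(as.vector(edges))
  prev <- setNames(rep(NA_integer_, length(nodes)), nodes)
  prev_edge <- setNames(rep(NA_integer_, length(nodes)), nodes)
  visited <- setNames(logical(length(nodes)), nodes)
  queue <- from
  visited[as.character(from)] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == to) break
    inc <- which(edges[, 1] == v | edges[, 2] == v)
    for (e in inc) {
      w <- if (edges[e, 1] == v) edges[e, 2] else edges[e, 1]
      if (!visited[as.character(w)]) {
        visited[as.character(w)] <- TRUE
        prev[as.character(w)] <- v
        prev_edge[as.character(w)] <- e
        queue <- c(queue, w)
      }
    }
  }
  path <- integer()
  v <- to
  while (v != from) {
    path <- c(path, prev_edge[as.character(v)])
    v <- prev[as.character(v)]
  }
  path
}

# Ordinary least-squares fit of edge lengths to a distance matrix; returns
# the residual sum of squares.
ls_residual <- function(edges, dm) {
  n <- nrow(dm)
  pairs <- utils::combn(n, 2)
  X <- matrix(0, ncol(pairs), nrow(edges))
  y <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    X[k, .tree_path(edges, i, j)] <- 1
    y[k] <- dm[i, j]
  }
  fit <- qr.coef(qr(X), y)
  fit[is.na(fit)] <- 0
  sum((y - X %*% fit)^2)
}

# Bipartition signatures (same canonical form as tree_bipartitions) of an
# edge-matrix topology, for labels[1..n] on leaves 1..n.
edges_bipartitions <- function(edges, labels) {
  n <- length(labels)
  anchor <- sort(labels)[1]
  sigs <- character()
  for (e in seq_len(nrow(edges))) {
    sub <- edges[-e, , drop = FALSE]
    # leaves reachable from edges[e,1] without crossing edge e
    reach <- edges[e, 1]
    repeat {
      inc <- sub[sub[, 1] %in% reach | sub[, 2] %in% reach, , drop = FALSE]
      new <- setdiff(unique(as.vector(inc)), reach)
      if (!length(new)) break
      reach <- c(reach, new)
    }
    side <- labels[intersect(reach, seq_len(n))]
    if (anchor %in% side) side <- setdiff(labels, side)
    if (length(side) < 2 || length(side) > n - 2) next
    sigs <- c(sigs, paste(sort(side), collapse = "|"))
  }
  unique(sigs)
}

# Best least-squares topology for a distance matrix, as bipartition set.
oracle_best_topology <- function(dm) {
  n <- nrow(dm)
  topos <- enumerate_topologies(n)
  res <- vapply(topos, ls_residual, numeric(1), dm = dm)
  edges_bipartitions(topos[[which.min(res)]], rownames(dm))
}

# Random additive distance matrix from a random unrooted tree with positive
# branch lengths; returns both the matrix and the generating bipartitions.
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tree <- ape::rtree(n, rooted = FALSE,
                     br = function(k) stats::runif(k, 0.3, 1.5))
  tree$tip.label <- LETTERS[seq_len(n)]
  dm <- ape::cophenetic.phylo(tree)
  dm <- dm[LETTERS[seq_len(n)], LETTERS[seq_len(n)]]
  list(dm = dm, tree = tree)
}

# Expected proportion of differing sites between two leaves joined by
# branches t1, t2 under the package's per-branch substitution model.
expected_p_two_taxa <- function(t1, t2) {
  q1 <- 1 - exp(-t1); q2 <- 1 - exp(-t2)
  q1 * (1 - q2) + q2 * (1 - q1) + q1 * q2 * (18 / 19)
}

# Small deterministic alignment fixtures
clean_four_taxon_alignment <- function() {
  as_alignment(c(
    A = paste0(strrep("A", 10), strrep("C", 10)),
    B = paste0(strrep("A", 10), strrep("C", 10)),
    C = paste0(strrep("A", 10), strrep("G", 10)),
    D = paste0(strrep("A", 10), strrep("G", 10))
  ))
}

eight_taxon_tree <- function() {
  paste0("(((A:0.08,B:0.08):0.06,(C:0.08,D:0.08):0.06):0.05,",
         "((E:0.08,F:0.08):0.06,(G:0.08,H:0.08):0.06):0.05);")
}
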