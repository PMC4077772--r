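# Ground-truthed synthetic data generators. Each generator is a pure
# function of (seed, parameters): precursor cDNAs that the annotation chain
# must recover exactly at zero noise, MALDI-like spectra with Gaussian m/z
# error plus uniform noise peaks, alignments evolved on a tree under a
# Poisson-style amino-acid model, and gene tables with a planted fraction of
# shared ortholog neighbors.

# Residues safe for peptide bodies and spacers: no basics (would create
# cuts), no G (reserved for the amide donor), no L (would turn a PQRF tail
# into an accidental LPXRF), and nothing hydrophobic enough to out-score the
# designed signal-peptide core.
.BODY_SET <- c("A", "D", "E", "H", "N", "Q", "S", "T", "W", "Y", "P")

# Codon table for reverse translation (flat synonymous-codon choice).
.codons_for <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Generate a ground-truthed precursor cDNA
#'
#' Builds a prepropeptide with a hydrophobic signal leader that satisfies the
#' package's own hydropathy/(-3,-1) predictor, followed by `n_peptides`
#' mature peptides, each preceded by a dibasic convertase site and followed
#' by an amide-donor glycine plus a basic flank drawn from `flank_motifs`.
#' The protein is reverse-translated with uniformly chosen synonymous codons
#' and wrapped in pyrimidine UTRs. The zero-noise contract holds:
#' [annotate_precursor()] at default settings recovers the truth exactly.
#'
#' @param seed RNG seed.
#' @param n_peptides number of mature peptides (>= 0).
#' @param family `"PQRFa"` or `"LPXRFa"`; sets the C-terminal motif.
#' @param flank_motifs C-flank kinds to cycle through, a subset of
#'   `c("glycine_basic", "dibasic", "KXXR")`.
#' @return Object of class `precursor_truth`: list with `id`, `cdna`,
#'   `protein`, `signal_end`, `orf_start`, `orf_end` (0-based half-open,
#'   stop excluded) and `peptides` (data frame `sequence`, `start`, `end`,
#'   `amidated`, `family`).
#' @export
generate_precursor_cdna <- function(seed, n_peptides = 3,
                                    family = c("PQRFa", "LPXRFa"),
                                    flank_motifs = c("glycine_basic",
                                                     "dibasic", "KXXR")) {
  family <- match.arg(family)
  stopifnot(n_peptides >= 0)
  flank_motifs <- match.arg(flank_motifs, several.ok = TRUE)
  .with_seed(seed, {
    leader <- paste0("M", strrep("L", 12), "A")  # 14 aa, cut after the A
    signal_end <- nchar(leader)
    flank_seq <- c(glycine_basic = "R", dibasic = "KR", KXXR = "KVSR")
    parts <- leader
    cursor <- nchar(leader)
    pep_rows <- list()
    if (n_peptides > 0) {
      for (i in seq_len(n_peptides)) {
        body <- paste(sample(.BODY_SET, sample(3:8, 1L), replace = TRUE),
                      collapse = "")
        suffix <- switch(family,
                         PQRFa = "PQRF",
                         LPXRFa = sample(c("LPLRF", "LPQRF"), 1L))
        pep <- paste0(body, suffix)
        kind <- flank_motifs[(i - 1L) %% length(flank_motifs) + 1L]
        nflank <- "KR"
        cflank <- paste0("G", flank_seq[[kind]])
        spacer <- paste(sample(.BODY_SET, sample(0:2, 1L), replace = TRUE),
                        collapse = "")
        parts <- c(parts, nflank, pep, cflank, spacer)
        start <- cursor + nchar(nflank)
        pep_rows[[i]] <- data.frame(
          sequence = pep, start = start, end = start + nchar(pep),
          amidated = TRUE, family = family, stringsAsFactors = FALSE)
        cursor <- start + nchar(pep) + nchar(cflank) + nchar(spacer)
      }
    }
    if (n_peptides == 0) parts <- c(parts, "SATE")  # keep a mature stub
    protein <- paste(parts, collapse = "")
    peptides <- if (length(pep_rows)) {
      do.call(rbind, pep_rows)
    } else {
      data.frame(sequence = character(), start = integer(), end = integer(),
                 amidated = logical(), family = character(),
                 stringsAsFactors = FALSE)
    }
    codons <- .codons_for()
    utr5 <- paste(sample(c("C", "T"), 8, replace = TRUE), collapse = "")
    utr3 <- paste(sample(c("C", "T"), 40, replace = TRUE), collapse = "")
    aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
    # redraw synonymous codons if an out-of-frame ATG happens to open a
    # longer (incomplete) reading frame than the designed one
    for (attempt in 1:25) {
      coding <- paste(vapply(aa, function(x) sample(codons[[x]], 1L),
                             character(1L)), collapse = "")
      cdna <- paste0(utr5, coding, sample(c("TAA", "TAG", "TGA"), 1L), utr3)
      orfs <- find_orfs(cdna, min_codons = max(2L, nchar(protein)))
      if (nrow(orfs) && orfs$protein[1L] == protein) break
    }
    if (!nrow(orfs) || orfs$protein[1L] != protein) {
      stop("generation error: designed ORF not dominant after 25 redraws",
           call. = FALSE)
    }
    out <- list(id = sprintf("synthetic_precursor_seed%d", as.integer(seed)),
                cdna = cdna, protein = protein, signal_end = signal_end,
                orf_start = nchar(utr5),
                orf_end = nchar(utr5) + nchar(coding),
                peptides = peptides)
    class(out) <- "precursor_truth"
    out
  })
}

#' Simulate a MALDI-TOF peak list
#'
#' The precursor `[M+H]+` and the complete singly charged b/y ladder of each
#' peptide are perturbed by Gaussian m/z error; uniform noise peaks are added
#' across `mz_range`; intensities are log-normal.
#'
#' @param peptides data frame with columns `sequence` and `amidated`, or a
#'   character vector of sequences (then taken as amidated).
#' @param sd Gaussian m/z error standard deviation in Da (>= 0).
#' @param n_noise number of uniform noise peaks.
#' @param mz_range noise m/z range (Da).
#' @param seed RNG seed.
#' @return List with `peaks` (data frame `mz`, `intensity`, sorted) and
#'   `truth` (list: `ions` data frame with `peptide`, `ion`, `true_mz`,
#'   `observed_mz`; `noise` data frame; `sd`; `seed`).
#' @export
simulate_maldi <- function(peptides, sd = 0.1, n_noise = 20,
                           mz_range = c(100, 2000), seed = 1) {
  stopifnot(sd >= 0, n_noise >= 0)
  if (is.character(peptides)) {
    peptides <- data.frame(sequence = peptides, amidated = TRUE,
                           stringsAsFactors = FALSE)
  }
  .with_seed(seed, {
    ions <- do.call(rbind, lapply(seq_len(nrow(peptides)), function(i) {
      ladder <- fragment_ladder(peptides$sequence[i],
                                amidated = peptides$amidated[i])
      data.frame(peptide = peptides$sequence[i],
                 ion = c("precursor", ladder$ions$ion),
                 true_mz = c(ladder$precursor_mz, ladder$ions$mz),
                 stringsAsFactors = FALSE)
    }))
    ions$observed_mz <- ions$true_mz + stats::rnorm(nrow(ions), 0, sd)
    ion_int <- stats::rlnorm(nrow(ions), log(100), 0.5)
    noise <- data.frame(
      mz = stats::runif(n_noise, mz_range[1L], mz_range[2L]),
      intensity = stats::rlnorm(n_noise, log(10), 0.5))
    peaks <- data.frame(mz = c(ions$observed_mz, noise$mz),
                        intensity = c(ion_int, noise$intensity))
    peaks <- .as_peak_list(peaks, "simulated_maldi")
    list(peaks = peaks,
         truth = list(ions = ions, noise = noise, sd = sd, seed = seed))
  })
}

#' Evolve an alignment along a tree
#'
#' The root sequence is uniform over the 20 residues; along each branch of
#' length t (expected substitutions/site) every site substitutes with
#' probability `1 - exp(-t)`, the replacement drawn uniformly from the other
#' 19 residues — the generative dual of the Poisson-corrected distance.
#'
#' @param tree a `phylo` object or Newick string with branch lengths.
#' @param n_columns number of alignment columns.
#' @param seed RNG seed.
#' @return Named character vector of leaf sequences (class `aa_alignment`
#'   when the tree has >= 3 tips).
#' @export
evolve_alignment <- function(tree, n_columns, seed = 1) {
  if (is.character(tree)) tree <- read_newick(text = tree)
  if (is.null(tree$edge.length)) {
    stop("tree must have branch lengths", call. = FALSE)
  }
  stopifnot(n_columns >= 1)
  .with_seed(seed, {
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    seqs <- vector("list", nnode)
    root <- ntip + 1L
    seqs[[root]] <- sample(.AA20, n_columns, replace = TRUE)
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      parent <- ord$edge[e, 1L]
      child <- ord$edge[e, 2L]
      t_len <- ord$edge.length[e]
      sq <- seqs[[parent]]
      q <- 1 - exp(-t_len)
      mask <- stats::runif(n_columns) < q
      nsub <- sum(mask)
      if (nsub > 0L) {
        ci <- match(sq[mask], .AA20)
        r <- sample.int(19L, nsub, replace = TRUE)
        sq[mask] <- .AA20[r + (r >= ci)]
      }
      seqs[[child]] <- sq
    }
    rows <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                   character(1L))
    names(rows) <- tree$tip.label
    if (ntip >= 3L) as_alignment(rows) else rows
  })
}

#' Generate paired gene tables with planted shared synteny
#'
#' Two single-scaffold gene tables with focal genes at the center; a
#' controlled fraction of the focal neighborhoods (window `k` per side) is
#' planted as ortholog pairs in conserved order.
#'
#' @param seed RNG seed.
#' @param n_genes genes per table (>= 2k + 1).
#' @param k neighborhood flank size.
#' @param shared_fraction fraction of the 2k focal neighbors planted as
#'   shared orthologs, in `[0, 1]`.
#' @return List with `table_a`, `table_b`, `orthology`, `focal_a`,
#'   `focal_b`, `n_planted`.
#' @export
generate_synteny_tables <- function(seed, n_genes = 60, k = 10,
                                    shared_fraction = 0.5) {
  stopifnot(shared_fraction >= 0, shared_fraction <= 1,
            n_genes >= 2 * k + 1)
  .with_seed(seed, {
    mk <- function(prefix, scaffold) {
      ids <- sprintf("%s%04d", prefix, seq_len(n_genes))
      data.frame(scaffold = scaffold,
                 start = (seq_len(n_genes) - 1L) * 1000L,
                 end = (seq_len(n_genes) - 1L) * 1000L + 500L,
                 gene_id = ids, score = 0L,
                 strand = sample(c("+", "-"), n_genes, replace = TRUE),
                 stringsAsFactors = FALSE)
    }
    ta <- mk("A", "scfA")
    tb <- mk("B", "scfB")
    mid <- (n_genes + 1L) %/% 2L
    focal_a <- ta$gene_id[mid]
    focal_b <- tb$gene_id[mid]
    nb_idx <- c((mid - k):(mid - 1L), (mid + 1L):(mid + k))
    n_planted <- round(shared_fraction * 2 * k)
    slots <- sort(sample(2L * k, n_planted))
    orth <- data.frame(gene_a = c(ta$gene_id[nb_idx][slots], focal_a),
                       gene_b = c(tb$gene_id[nb_idx][slots], focal_b),
                       stringsAsFactors = FALSE)
    list(table_a = ta, table_b = tb, orthology = as_orthology(orth),
         focal_a = focal_a, focal_b = focal_b, n_planted = n_planted)
  })
}
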