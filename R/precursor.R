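# Precursor annotation: ORF finding, signal peptide prediction, prohormone
# convertase cleavage, peptide excision/amidation and RFamide family calls.
#
# Coordinate convention: 0-based half-open internally (an ORF spanning the
# first two codons has start = 0, end = 6; a cleavage position is the 0-based
# index of the first residue after the cut). Printed reports are 1-based.

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read DNA sequences from a FASTA file
#'
#' @param path path to a (possibly multi-record) DNA FASTA file.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_dna_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    .check_residues(seqs[[i]], .DNA_ALPHABET, what = names(seqs)[i])
  }
  seqs
}

# Translate a vector of codon strings; codons containing N (or any non-ACGT
# base) give NA.
.translate_codons <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa
}

#' Find open reading frames on the forward strand
#'
#' Scans all three forward frames of an oriented cDNA for ORFs that begin at
#' ATG and run to the first in-frame stop codon. ORFs that reach the end of
#' the sequence without a stop are returned flagged as incomplete. Any codon
#' containing an ambiguity base N is untranslatable and the candidate ORF is
#' dropped.
#'
#' @param sequence uppercase DNA string over A,C,G,T,N.
#' @param min_codons minimum protein length (codons, stop excluded).
#' @return A data frame sorted by protein length (descending) with columns
#'   `start`, `end` (0-based half-open nucleotide span of the coding region,
#'   stop codon excluded), `frame` (0, 1 or 2), `protein` and `incomplete`.
#' @examples
#' find_orfs("ATGAAATAG", min_codons = 2)
#' @export
find_orfs <- function(sequence, min_codons = 50) {
  .check_residues(sequence, .DNA_ALPHABET, what = "sequence")
  stopifnot(min_codons >= 1)
  n <- nchar(sequence)
  out <- list()
  for (frame in 0:2) {
    n_codons <- (n - frame) %/% 3
    if (n_codons < 1L) next
    starts_nt <- frame + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(sequence, starts_nt + 1L, starts_nt + 3L)
    aa <- .translate_codons(codons)
    is_stop <- !is.na(aa) & aa == "*"
    is_bad <- is.na(aa)  # codon contains N
    atg <- which(codons == "ATG")
    for (a in atg) {
      # first in-frame stop at or after the start codon
      stop_idx <- which(is_stop & seq_along(codons) > a)
      stop_idx <- if (length(stop_idx)) stop_idx[1L] else NA_integer_
      last <- if (is.na(stop_idx)) n_codons else stop_idx - 1L
      span <- a:last
      if (any(is_bad[span])) next
      protein <- paste(aa[span], collapse = "")
      if (nchar(protein) < min_codons) next
      out[[length(out) + 1L]] <- data.frame(
        start = starts_nt[a],
        end = starts_nt[last] + 3L,
        frame = frame,
        protein = protein,
        incomplete = is.na(stop_idx),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      protein = character(), incomplete = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(-nchar(res$protein), res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Kyte-Doolittle hydropathy profile
#'
#' Mean hydropathy over a sliding window.
#'
#' @param protein amino-acid string over the 20 standard residues.
#' @param window odd window width, at most the protein length.
#' @return Data frame with `center` (1-based index of the window center) and
#'   `hydropathy` (arithmetic mean of Kyte-Doolittle indices in the window).
#' @export
hydropathy_profile <- function(protein, window = 7) {
  chars <- .check_residues(protein, .AA20, what = "protein")
  n <- length(chars)
  if (window %% 2 != 1 || window < 1) stop("window must be odd and positive",
                                           call. = FALSE)
  if (window > n) stop("window exceeds protein length", call. = FALSE)
  vals <- .KYTE_DOOLITTLE[chars]
  cs <- cumsum(c(0, vals))
  starts <- seq_len(n - window + 1L)
  score <- (cs[starts + window] - cs[starts]) / window
  data.frame(center = starts + (window - 1L) %/% 2L, hydropathy = unname(score))
}

#' Predict a secretory signal peptide
#'
#' Heuristic predictor: locate the most hydrophobic window-`window` stretch
#' within the first `search_limit` residues (ties resolved N-terminally); if
#' its mean Kyte-Doolittle hydropathy reaches `threshold`, scan cut positions
#' from the end of that core up to `max_offset` residues downstream for a cut
#' satisfying the (-3,-1) rule (small residue at -1, small/aliphatic at -3).
#' The qualifying cut closest to the core is returned.
#'
#' @param protein amino-acid string starting with M.
#' @param window hydrophobic-core window width (odd).
#' @param threshold minimum mean hydropathy of the core.
#' @param search_limit number of N-terminal residues searched for the core.
#' @param max_offset how far past the core end a cut may fall.
#' @return Integer signal peptide length (equivalently the 0-based index of
#'   the first mature residue), or `NA_integer_` when no signal is predicted.
#' @export
predict_signal_peptide <- function(protein, window = 7, threshold = 1.6,
                                   search_limit = 40, max_offset = 8) {
  chars <- .check_residues(protein, .AA20, what = "protein")
  n <- length(chars)
  if (n < 15L) return(NA_integer_)
  region <- min(search_limit, n)
  if (region < window) return(NA_integer_)
  prof <- hydropathy_profile(substr(protein, 1L, region), window = window)
  best <- max(prof$hydropathy)
  if (best < threshold) return(NA_integer_)
  s <- which(prof$hydropathy >= best - 1e-12)[1L]  # 1-based window start
  core_end <- s + window - 1L                       # residues 1..core_end
  cand <- core_end:min(core_end + max_offset, n - 1L)
  cand <- cand[cand >= 3L]
  for (p in cand) {
    if (chars[p] %in% .SIGNAL_MINUS1 && chars[p - 2L] %in% .SIGNAL_MINUS3) {
      return(as.integer(p))
    }
  }
  NA_integer_
}

#' Find prohormone convertase cleavage sites
#'
#' Reports, ordered by position: dibasic pairs (KR, RR, KK, RK; cut after the
#' pair), tetrabasic convertase motifs \[K/R\]-X-X-R (cut after the final R;
#' the first X must not be proline or a bulky aromatic F/W/Y, which disfavour
#' cleavage), and single basic residues immediately preceded by an amide-donor
#' glycine (cut after the basic residue; these sites are amidation-competent).
#' Overlapping matches are all reported and deduplicated by (position, kind).
#'
#' @param protein amino-acid string.
#' @return Data frame with `position` (0-based index of the first residue
#'   after the cut), `motif` and `kind` (`dibasic`, `KXXR`, `glycine_basic`).
#' @examples
#' find_cleavage_sites("AAKVSRAA")
#' @export
find_cleavage_sites <- function(protein) {
  chars <- .check_residues(protein, .AA20, what = "protein")
  n <- length(chars)
  basic <- chars %in% c("K", "R")
  pos <- integer(); motif <- character(); kind <- character()
  add <- function(p, m, k) {
    pos <<- c(pos, p); motif <<- c(motif, m); kind <<- c(kind, k)
  }
  # dibasic pairs
  if (n >= 2L) {
    for (i in which(basic[-n] & basic[-1L])) {
      add(i + 1L, paste0(chars[i], chars[i + 1L]), "dibasic")
    }
  }
  # [K/R]XXR, cut after the final R
  if (n >= 4L) {
    for (i in seq_len(n - 3L)) {
      if (basic[i] && chars[i + 3L] == "R" &&
          !chars[i + 1L] %in% c("P", "F", "W", "Y")) {
        add(i + 3L, paste(chars[i:(i + 3L)], collapse = ""), "KXXR")
      }
    }
  }
  # single basic preceded by amide-donor G
  for (i in which(basic)) {
    if (i >= 2L && chars[i - 1L] == "G") {
      add(i, paste0("G", chars[i]), "glycine_basic")
    }
  }
  out <- data.frame(position = pos, motif = motif, kind = kind,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("position", "kind")]), , drop = FALSE]
  out <- out[order(out$position, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a peptide into an RFamide family
#'
#' Family membership is a function of the C-terminal residues and the
#' amidation flag only. Non-amidated peptides are `other`; otherwise suffixes
#' are tested in priority order LPXRFa (ends LPLRF or LPQRF), PQRFa (ends
#' PQRF), RFa (ends RF).
#'
#' @param sequence peptide sequence (post-trim, no donor glycine).
#' @param amidated logical amidation flag.
#' @return One of `"PQRFa"`, `"LPXRFa"`, `"RFa"`, `"other"`.
#' @export
classify_rfamide_family <- function(sequence, amidated) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!isTRUE(amidated)) return("other")
  if (grepl("LP[LQ]RF$", sequence)) return("LPXRFa")
  if (endsWith(sequence, "PQRF")) return("PQRFa")
  if (endsWith(sequence, "RF")) return("RFa")
  "other"
}

#' Excise mature peptides from a precursor
#'
#' Candidate segments are the intervals between consecutive cut points (the
#' signal peptide boundary and the protein end close the first and last
#' interval). Basic residues of the flanking motifs are stripped from segment
#' ends; a residual C-terminal glycine followed in the precursor by a basic
#' residue is the amide donor and is trimmed with `amidated = TRUE`. Segments
#' shorter than `min_len` or longer than `max_len` after trimming are
#' discarded, as is everything when the precursor carries no cut site at all
#' (an uncut protein is not a processed peptide).
#'
#' @param protein precursor amino-acid string.
#' @param signal_end signal peptide length (0-based first mature residue), or
#'   `NA` when no signal was predicted (extraction then starts at 0).
#' @param sites cleavage site data frame from [find_cleavage_sites()].
#' @param min_len,max_len retained peptide length bounds.
#' @return Data frame with `sequence`, `start`, `end` (0-based half-open span
#'   of the trimmed peptide in the precursor), `amidated`, `family`,
#'   `n_flank_motif`, `c_flank_motif`.
#' @export
extract_mature_peptides <- function(protein, signal_end, sites,
                                    min_len = 3, max_len = 50) {
  chars <- .check_residues(protein, .AA20, what = "protein")
  n <- length(chars)
  if (!is.na(signal_end) && signal_end > n) {
    stop("signal_end beyond protein length", call. = FALSE)
  }
  empty <- data.frame(sequence = character(), start = integer(),
                      end = integer(), amidated = logical(),
                      family = character(), n_flank_motif = character(),
                      c_flank_motif = character(), stringsAsFactors = FALSE)
  if (is.null(sites) || nrow(sites) == 0L) return(empty)
  origin <- if (is.na(signal_end)) 0L else as.integer(signal_end)
  enz <- sites$position[sites$position >= origin]
  if (!length(enz)) return(empty)
  cuts <- sort(unique(c(origin, enz, n)))
  motif_at <- function(p) {
    m <- sites$motif[sites$position == p]
    if (length(m)) paste(unique(m), collapse = "/") else ""
  }
  out <- list()
  for (i in seq_len(length(cuts) - 1L)) {
    b1 <- cuts[i]; b2 <- cuts[i + 1L]
    lo <- b1 + 1L; hi <- b2            # 1-based inclusive residue span
    while (lo <= hi && chars[lo] %in% c("K", "R")) lo <- lo + 1L
    while (hi >= lo && chars[hi] %in% c("K", "R")) hi <- hi - 1L
    if (hi < lo) next
    amidated <- FALSE
    if (chars[hi] == "G" && hi < n && chars[hi + 1L] %in% c("K", "R")) {
      amidated <- TRUE
      hi <- hi - 1L
      if (hi < lo) next
    }
    len <- hi - lo + 1L
    if (len < min_len || len > max_len) next
    sq <- paste(chars[lo:hi], collapse = "")
    out[[length(out) + 1L]] <- data.frame(
      sequence = sq, start = lo - 1L, end = hi,
      amidated = amidated,
      family = classify_rfamide_family(sq, amidated),
      n_flank_motif = motif_at(b1), c_flank_motif = motif_at(b2),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate a neuropeptide precursor from cDNA
#'
#' Deterministic composition of the annotation chain: longest forward-strand
#' ORF, translation, signal peptide prediction, convertase cleavage mapping,
#' peptide excision/amidation and family classification.
#'
#' @param sequence uppercase cDNA string (oriented, forward strand).
#' @param id record identifier carried into reports.
#' @param min_codons minimum ORF length passed to [find_orfs()].
#' @param ... further arguments passed to [predict_signal_peptide()].
#' @return An object of class `precursor_annotation`: a list with `id`,
#'   `orf` (one-row data frame or `NULL` when no ORF qualifies), `signal_end`,
#'   `cleavage_sites` and `peptides`.
#' @export
annotate_precursor <- function(sequence, id = "precursor", min_codons = 50,
                               ...) {
  orfs <- find_orfs(sequence, min_codons = min_codons)
  if (nrow(orfs) == 0L) {
    res <- list(id = id, orf = NULL, signal_end = NA_integer_,
                cleavage_sites = NULL, peptides = NULL)
    class(res) <- "precursor_annotation"
    return(res)
  }
  orf <- orfs[1L, , drop = FALSE]
  protein <- orf$protein
  signal_end <- predict_signal_peptide(protein, ...)
  sites <- find_cleavage_sites(protein)
  peptides <- extract_mature_peptides(protein, signal_end, sites)
  res <- list(id = id, orf = orf, signal_end = signal_end,
              cleavage_sites = sites, peptides = peptides)
  class(res) <- "precursor_annotation"
  res
}

#' @export
print.precursor_annotation <- function(x, ...) {
  cat("Precursor annotation:", x$id, "\n")
  if (is.null(x$orf)) {
    cat("  no qualifying ORF\n")
    return(invisible(x))
  }
  # reports are 1-based inclusive
  cat(sprintf("  ORF: nt %d-%d (frame %d), %d aa%s\n",
              x$orf$start + 1L, x$orf$end, x$orf$frame,
              nchar(x$orf$protein),
              if (x$orf$incomplete) ", incomplete (no stop)" else ""))
  if (is.na(x$signal_end)) {
    cat("  signal peptide: none predicted\n")
  } else {
    cat(sprintf("  signal peptide: %d aa (cut after residue %d)\n",
                x$signal_end, x$signal_end))
  }
  np <- if (is.null(x$peptides)) 0L else nrow(x$peptides)
  cat(sprintf("  %d cleavage site(s), %d mature peptide(s)\n",
              if (is.null(x$cleavage_sites)) 0L else nrow(x$cleavage_sites),
              np))
  if (np) {
    for (i in seq_len(np)) {
      p <- x$peptides[i, ]
      cat(sprintf("    %s  aa %d-%d  %s%s\n", p$sequence,
                  p$start + 1L, p$end, p$family,
                  if (p$amidated) " (amidated)" else ""))
    }
  }
  invisible(x)
}

#' Longest common C-terminal suffix
#'
#' @param sequences character vector of peptide sequences.
#' @return The longest string that is a suffix of every input (possibly "").
#' @examples
#' longest_common_csuffix(c("WDEAWRPQRF", "GDHTKDGWRPQRF", "GRDQGWRPQRF"))
#' @export
longest_common_csuffix <- function(sequences) {
  stopifnot(length(sequences) >= 1L)
  k <- 0L
  maxk <- min(nchar(sequences))
  while (k < maxk) {
    tails <- substring(sequences, nchar(sequences) - k, nchar(sequences))
    if (length(unique(tails)) > 1L) break
    k <- k + 1L
  }
  if (k == 0L) "" else substring(sequences[1L], nchar(sequences[1L]) - k + 1L)
}

#' Tabulate predicted peptides across annotations
#'
#' @param annotations a `precursor_annotation` or list of them.
#' @return Data frame with 1-based inclusive coordinates, one row per
#'   predicted peptide (columns `precursor_id`, `peptide_seq`, `start_1based`,
#'   `end_1based`, `amidated`, `family`, `n_flank_motif`, `c_flank_motif`).
#' @export
peptide_table <- function(annotations) {
  if (inherits(annotations, "precursor_annotation")) {
    annotations <- list(annotations)
  }
  rows <- lapply(annotations, function(a) {
    if (is.null(a$peptides) || nrow(a$peptides) == 0L) return(NULL)
    data.frame(precursor_id = a$id, peptide_seq = a$peptides$sequence,
               start_1based = a$peptides$start + 1L,
               end_1based = a$peptides$end,
               amidated = a$peptides$amidated, family = a$peptides$family,
               n_flank_motif = a$peptides$n_flank_motif,
               c_flank_motif = a$peptides$c_flank_motif,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) {
    return(data.frame(precursor_id = character(), peptide_seq = character(),
                      start_1based = integer(), end_1based = integer(),
                      amidated = logical(), family = character(),
                      n_flank_motif = character(), c_flank_motif = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
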