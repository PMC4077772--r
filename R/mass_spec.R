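# Theoretical peptide masses, singly charged b/y fragment ladders, and
# tolerance-based assignment against MALDI-TOF / post-source-decay peak lists.

#' Monoisotopic mass of a peptide
#'
#' Sum of residue masses plus one water, minus the OH-to-NH2 delta when the
#' C-terminus is amidated.
#'
#' @param sequence peptide string over the 20 standard residues (vectorized).
#' @param amidated logical; C-terminal amide instead of free acid.
#' @param monoisotopic use monoisotopic masses (default) or average masses.
#' @return Neutral mass in Da.
#' @examples
#' peptide_monoisotopic_mass("WDEAWRPQRF", amidated = TRUE)
#' @export
peptide_monoisotopic_mass <- function(sequence, amidated = FALSE,
                                      monoisotopic = TRUE) {
  tab <- residue_masses(monoisotopic)
  vapply(sequence, function(sq) {
    chars <- .check_residues(sq, .AA20, what = "sequence")
    sum(tab$residues[chars]) + tab$water +
      if (isTRUE(amidated)) tab$amide_delta else 0
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Singly protonated m/z
#'
#' @param neutral_mass neutral monoisotopic mass (Da).
#' @return `[M+H]+` m/z, i.e. mass plus one proton (1.007276 Da).
#' @export
singly_protonated_mz <- function(neutral_mass) {
  stopifnot(is.numeric(neutral_mass))
  neutral_mass + .PROTON
}

#' Singly charged b/y fragment-ion ladder
#'
#' b_i is the protonated N-terminal fragment of the first i residues; y_i the
#' protonated C-terminal fragment of the last i residues (carrying the amide
#' when the peptide is amidated). Only singly charged b/y ions are produced,
#' matching post-source decay on MALDI.
#'
#' @param sequence peptide string, length >= 2.
#' @param amidated logical C-terminal amidation flag.
#' @param monoisotopic use monoisotopic (default) or average masses.
#' @return Object of class `fragment_ladder`: list with `sequence`,
#'   `amidated`, `precursor_mz` and a data frame `ions` (columns `ion`,
#'   `series`, `index`, `mz`) for i = 1..n-1 in both series.
#' @export
fragment_ladder <- function(sequence, amidated = FALSE, monoisotopic = TRUE) {
  chars <- .check_residues(sequence, .AA20, what = "sequence")
  n <- length(chars)
  if (n < 2L) stop("fragment ladder needs a peptide of length >= 2",
                   call. = FALSE)
  tab <- residue_masses(monoisotopic)
  m <- tab$residues[chars]
  cterm <- tab$water + if (isTRUE(amidated)) tab$amide_delta else 0
  b <- cumsum(m)[seq_len(n - 1L)] + tab$proton
  y <- rev(cumsum(rev(m)))[-1L] + cterm + tab$proton  # y_{n-1} .. y_1
  y <- rev(y)                                          # y_1 .. y_{n-1}
  ions <- data.frame(
    ion = c(paste0("b", seq_len(n - 1L)), paste0("y", seq_len(n - 1L))),
    series = rep(c("b", "y"), each = n - 1L),
    index = c(seq_len(n - 1L), seq_len(n - 1L)),
    mz = unname(c(b, y)),
    stringsAsFactors = FALSE
  )
  out <- list(sequence = sequence, amidated = isTRUE(amidated),
              precursor_mz = sum(m) + cterm + tab$proton, ions = ions)
  class(out) <- "fragment_ladder"
  out
}

#' Read a mass-spectral peak list
#'
#' Two-column whitespace/tab separated text (m/z, intensity). Lines starting
#' with `#` are ignored. Peaks are validated (m/z > 0, intensity >= 0) and
#' sorted ascending by m/z.
#'
#' @param path path to the peak list file.
#' @param source_id identifier attached to the result.
#' @return Data frame with columns `mz` and `intensity`, attribute
#'   `source_id`.
#' @export
read_peak_list <- function(path, source_id = basename(path)) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("mz", "intensity"),
                          colClasses = "numeric")
  .as_peak_list(df, source_id)
}

.as_peak_list <- function(df, source_id = "peaks") {
  if (nrow(df) && (any(!is.finite(df$mz)) || any(df$mz <= 0))) {
    stop("peak m/z values must be strictly positive", call. = FALSE)
  }
  if (nrow(df) && any(df$intensity < 0)) {
    stop("peak intensities must be >= 0", call. = FALSE)
  }
  df <- df[order(df$mz), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "source_id") <- source_id
  df
}

#' Read spectra from an MGF file
#'
#' Minimal Mascot generic format reader: one spectrum per BEGIN IONS/END IONS
#' block; TITLE and PEPMASS are honoured, other headers ignored.
#'
#' @param path path to the MGF file.
#' @return List of peak-list data frames (see [read_peak_list()]), each with
#'   attributes `source_id` (TITLE or block index) and `pepmass` (or `NA`).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(starts) != length(ends) || any(ends < starts)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS", call. = FALSE)
  }
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    title <- sub("^TITLE=", "", grep("^TITLE=", block, value = TRUE))
    pepmass <- sub("^PEPMASS=", "", grep("^PEPMASS=", block, value = TRUE))
    peaks <- block[!grepl("=", block, fixed = TRUE) & nzchar(trimws(block))]
    fields <- strsplit(trimws(peaks), "\\s+")
    df <- data.frame(
      mz = vapply(fields, function(f) as.numeric(f[1L]), numeric(1L)),
      intensity = vapply(fields, function(f) {
        if (length(f) >= 2L) as.numeric(f[2L]) else 1
      }, numeric(1L))
    )
    id <- if (length(title)) title[1L] else paste0("spectrum_", i)
    pl <- .as_peak_list(df, id)
    attr(pl, "pepmass") <- if (length(pepmass)) {
      as.numeric(strsplit(pepmass[1L], "\\s+")[[1L]][1L])
    } else {
      NA_real_
    }
    out[[i]] <- pl
  }
  names(out) <- vapply(out, attr, character(1L), "source_id")
  out
}

#' Match a fragment ladder to an observed peak list
#'
#' Each theoretical ion is assigned its nearest observed peak when within
#' `tolerance`; an observed peak may serve several theoretical ions only when
#' their theoretical m/z lie within `tolerance` of each other, in which case
#' the assignments are flagged ambiguous.
#'
#' @param peaks peak-list data frame (`mz`, `intensity`).
#' @param ladder a [fragment_ladder()].
#' @param tolerance absolute assignment tolerance in Da (> 0).
#' @return Object of class `match_result`: list with `assignments` (data
#'   frame: `ion`, `theoretical_mz`, `observed_mz`, `error`, `ambiguous`),
#'   `coverage` (matched fraction of theoretical ions) and `n_theoretical`.
#' @export
match_peaks <- function(peaks, ladder, tolerance = 0.5) {
  stopifnot(inherits(ladder, "fragment_ladder"))
  if (!is.numeric(tolerance) || tolerance <= 0) {
    stop("tolerance must be > 0", call. = FALSE)
  }
  theo <- ladder$ions
  if (nrow(peaks) == 0L) {
    res <- list(assignments = data.frame(ion = character(),
                                         theoretical_mz = numeric(),
                                         observed_mz = numeric(),
                                         error = numeric(),
                                         ambiguous = logical(),
                                         stringsAsFactors = FALSE),
                coverage = 0, n_theoretical = nrow(theo))
    class(res) <- "match_result"
    return(res)
  }
  nearest <- vapply(theo$mz, function(mz) which.min(abs(peaks$mz - mz)),
                    integer(1L))
  err <- peaks$mz[nearest] - theo$mz
  hit <- abs(err) <= tolerance
  asn <- data.frame(ion = theo$ion[hit],
                    theoretical_mz = theo$mz[hit],
                    observed_mz = peaks$mz[nearest[hit]],
                    error = err[hit],
                    ambiguous = rep(FALSE, sum(hit)),
                    stringsAsFactors = FALSE)
  # a shared observed peak is legitimate only for near-degenerate theory
  if (nrow(asn) > 1L) {
    dup_peaks <- unique(asn$observed_mz[duplicated(asn$observed_mz)])
    for (p in dup_peaks) {
      idx <- which(asn$observed_mz == p)
      tmz <- asn$theoretical_mz[idx]
      if (diff(range(tmz)) < tolerance) {
        asn$ambiguous[idx] <- TRUE
      } else {
        # keep only the closest assignment for this peak
        keep <- idx[which.min(abs(asn$error[idx]))]
        drop <- setdiff(idx, keep)
        asn <- asn[-drop, , drop = FALSE]
      }
    }
  }
  res <- list(assignments = asn,
              coverage = nrow(asn) / nrow(theo),
              n_theoretical = nrow(theo))
  class(res) <- "match_result"
  res
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Fragment match: %d/%d theoretical ions assigned (coverage %.3f)\n",
              nrow(x$assignments), x$n_theoretical, x$coverage))
  invisible(x)
}

#' Identify peptides in a spectrum
#'
#' Scores each candidate peptide against an observed peak list: the precursor
#' `[M+H]+` is looked up within `tolerance`, then the b/y ladder is matched.
#' Candidates are ranked by precursor hit, then fragment coverage
#' (descending), then absolute precursor error, with the sequence string as
#' the final deterministic tie-break.
#'
#' @param peaks peak-list data frame.
#' @param candidates data frame with columns `sequence` and `amidated`.
#' @param tolerance assignment tolerance in Da.
#' @return Data frame ranked best-first with columns `sequence`, `amidated`,
#'   `precursor_mz`, `precursor_matched`, `precursor_error`, `coverage`; the
#'   per-candidate `match_result` objects are attached as attribute
#'   `"matches"` (in ranked order).
#' @export
identify_peptides <- function(peaks, candidates, tolerance = 0.5) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    stop("candidates must be a non-empty data frame", call. = FALSE)
  }
  stopifnot(all(c("sequence", "amidated") %in% names(candidates)))
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    sq <- candidates$sequence[i]
    am <- candidates$amidated[i]
    ladder <- fragment_ladder(sq, amidated = am)
    mres <- match_peaks(peaks, ladder, tolerance = tolerance)
    perr <- NA_real_
    pmatched <- FALSE
    if (nrow(peaks)) {
      j <- which.min(abs(peaks$mz - ladder$precursor_mz))
      e <- peaks$mz[j] - ladder$precursor_mz
      if (abs(e) <= tolerance) {
        perr <- e
        pmatched <- TRUE
      }
    }
    list(row = data.frame(sequence = sq, amidated = am,
                          precursor_mz = ladder$precursor_mz,
                          precursor_matched = pmatched,
                          precursor_error = perr,
                          coverage = mres$coverage,
                          stringsAsFactors = FALSE),
         match = mres)
  })
  df <- do.call(rbind, lapply(rows, `[[`, "row"))
  ord <- order(!df$precursor_matched, -df$coverage,
               ifelse(is.na(df$precursor_error), Inf,
                      abs(df$precursor_error)),
               df$sequence)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "matches") <- lapply(rows, `[[`, "match")[ord]
  df
}
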