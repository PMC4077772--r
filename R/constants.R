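# Physical constants and per-residue tables used across the package.
# Monoisotopic residue masses are the standard values for the 20 proteinogenic
# amino acids (Da, neutral residue, i.e. amino acid minus water).

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.MONO_MASS <- c(
  A = 71.0371138, C = 103.0091848, D = 115.0269430, E = 129.0425931,
  F = 147.0684139, G = 57.0214637, H = 137.0589119, I = 113.0840640,
  K = 128.0949630, L = 113.0840640, M = 131.0404849, N = 114.0429274,
  P = 97.0527638, Q = 128.0585775, R = 156.1011110, S = 87.0320284,
  T = 101.0476785, V = 99.0684139, W = 186.0793129, Y = 163.0633285
)

.AVG_MASS <- c(
  A = 71.07802, C = 103.14281, D = 115.08757, E = 129.11418,
  F = 147.17420, G = 57.05140, H = 137.13952, I = 113.15787,
  K = 128.17252, L = 113.15787, M = 131.19604, N = 114.10280,
  P = 97.11537, Q = 128.12942, R = 156.18592, S = 87.07742,
  T = 101.10404, V = 99.13125, W = 186.21031, Y = 163.17360
)

.WATER_MONO <- 18.010565
.WATER_AVG <- 18.015286
.PROTON <- 1.007276
# C-terminal amidation replaces the free-acid OH by NH2.
.AMIDE_DELTA <- -0.984016

# Kyte-Doolittle hydropathy indices.
.KYTE_DOOLITTLE <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

# von Heijne-style residue sets for the (-3,-1) rule: small residues allowed
# at -1 and small/aliphatic residues at -3 relative to the signal cut.
.SIGNAL_MINUS1 <- c("A", "G", "S", "C", "T", "Q")
.SIGNAL_MINUS3 <- c("A", "V", "S", "C", "T", "G", "I", "L")

#' Residue mass table
#'
#' Monoisotopic (default) or average masses of the 20 standard amino acid
#' residues, plus the constants used for peptide mass computation.
#'
#' @param monoisotopic logical; return monoisotopic (`TRUE`) or average masses.
#' @return A list with elements `residues` (named numeric vector of 20 residue
#'   masses, Da), `water`, `proton` and `amide_delta` (Da). `amide_delta` is
#'   the mass change of C-terminal amidation (OH -> NH2), a negative number.
#' @examples
#' residue_masses()$residues[["G"]]
#' @export
residue_masses <- function(monoisotopic = TRUE) {
  list(
    residues = if (monoisotopic) .MONO_MASS else .AVG_MASS,
    water = if (monoisotopic) .WATER_MONO else .WATER_AVG,
    proton = .PROTON,
    amide_delta = .AMIDE_DELTA
  )
}

# Split a sequence string into single-character residues, validating against
# an allowed alphabet. `what` names the offending input in error messages.
.check_residues <- function(sequence, alphabet = .AA20, what = "sequence") {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    stop(what, " must be a non-empty string", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% alphabet)
  if (length(bad)) {
    stop("unknown residue '", chars[bad[1L]], "' at position ", bad[1L],
         " of ", what, call. = FALSE)
  }
  chars
}

# Restore the caller-visible RNG state on exit so seeded generators do not
# perturb the global stream.
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
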