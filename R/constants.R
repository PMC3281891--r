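# Residue alphabet, background composition and hydropathy constants shared
# across the package.  All scoring is closed over the 20 standard letters;
# 'X' is the only extra letter and always scores as background (0 log-odds).

#' @rdname pqfam_constants
#' @format NULL
#' @keywords internal
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Swiss-Prot-like average amino-acid composition, renormalised to sum to 1.
AA_BACKGROUND_RAW <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0672, F = 0.0386,
  G = 0.0708, H = 0.0227, I = 0.0591, K = 0.0580, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0475, Q = 0.0393, R = 0.0553,
  S = 0.0665, T = 0.0536, V = 0.0686, W = 0.0110, Y = 0.0292)

#' Background amino-acid composition
#'
#' Average composition of well-curated protein databases, renormalised to
#' sum to one, in the fixed alphabet order used throughout the package.
#' Used as the null emission model for scoring, calibration and the
#' synthetic generator's loop/terminus residues.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aa_background <- function() {
  bg <- AA_BACKGROUND_RAW[AA_ALPHABET]
  bg / sum(bg)
}

#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector over the 20 standard amino acids.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8,
    G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8,
    M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
    S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)[AA_ALPHABET]
}

# Residues with positive Kyte-Doolittle values plus the aromatics W and Y;
# carries 85% of the emission mass inside synthetic TM helices.
HYDRO_SET <- c("A", "C", "F", "I", "L", "M", "V", "W", "Y")

#' Helix emission distribution of the synthetic generator
#'
#' Transmembrane helices of the synthetic families draw residues from a
#' hydrophobic-biased distribution: 85% of the mass sits on
#' \{A,C,F,I,L,M,V,W,Y\}, distributed within that set proportionally to
#' background frequency times exp(KD/1.4) (a Boltzmann tilt toward the
#' strongly hydrophobic aliphatics I, L and V that dominate TM cores, so
#' that the windowed hydropathy of a pure helix clears the standard
#' helix-calling threshold with margin); the remaining 15% is background
#' over all 20 residues.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
helix_distribution <- function() {
  bg <- aa_background()
  kd <- kyte_doolittle()
  w <- bg[HYDRO_SET] * exp(kd[HYDRO_SET] / 1.4)
  w <- 0.85 * w / sum(w)
  out <- 0.15 * bg
  out[HYDRO_SET] <- out[HYDRO_SET] + w
  out
}

# Map non-standard residue letters onto the closed alphabet.  B/Z/U/O (and
# any other unknown letter) become X, which scores as background.
normalize_residues <- function(x, warn = TRUE) {
  up <- toupper(x)
  up <- gsub("[*.]", "", up)
  bad <- gsub(paste0("[", paste(AA_ALPHABET, collapse = ""), "X-]"), "", up)
  if (warn && any(nzchar(bad))) {
    letters_seen <- sort(unique(strsplit(paste(bad, collapse = ""), "")[[1]]))
    warning("non-standard residue letter(s) ", paste(letters_seen, collapse = ", "),
            " mapped to X", call. = FALSE)
  }
  gsub(paste0("[^", paste(AA_ALPHABET, collapse = ""), "X-]"), "X", up)
}

# Integer encoding: 1..20 in alphabet order, 21 = X.  Gap characters are not
# allowed here; strip them first.
encode_residues <- function(seq) {
  codes <- match(strsplit(seq, "")[[1]], c(AA_ALPHABET, "X"))
  if (anyNA(codes)) stop("sequence contains letters outside the closed alphabet")
  codes
}
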