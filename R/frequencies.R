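#' Amino-acid alphabets and packaged composition tables
#'
#' The scanner works over the 20 canonical amino acids. Ambiguity and
#' non-standard codes (B, Z, J, X, U, O and the stop character `*`)
#' contribute a log-likelihood ratio of 0 and are excluded from frequency
#' estimation.
#'
#' @name aa-alphabet
NULL

#' @rdname aa-alphabet
#' @export
CANONICAL_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname aa-alphabet
#' @export
AMBIGUOUS_AA <- c("B", "Z", "J", "X", "U", "O", "*")

.normalize_freqs <- function(x) {
  x <- x[CANONICAL_AA]
  x / sum(x)
}

# Q/N-rich composition typical of experimentally characterized yeast
# prion-forming domains. Packaged default; override via the `foreground`
# argument of build_llr_table().
.PRION_FG_RAW <- c(
  A = 0.043, C = 0.002, D = 0.025, E = 0.023, F = 0.031,
  G = 0.074, H = 0.018, I = 0.020, K = 0.030, L = 0.031,
  M = 0.022, N = 0.167, P = 0.048, Q = 0.206, R = 0.019,
  S = 0.095, T = 0.031, V = 0.020, W = 0.005, Y = 0.045
)

# Whole-proteome composition in the style of the S. cerevisiae proteome;
# the packaged default background.
.DEFAULT_BG_RAW <- c(
  A = 0.055, C = 0.013, D = 0.058, E = 0.064, F = 0.045,
  G = 0.050, H = 0.022, I = 0.066, K = 0.073, L = 0.096,
  M = 0.021, N = 0.061, P = 0.044, Q = 0.039, R = 0.044,
  S = 0.090, T = 0.059, V = 0.056, W = 0.010, Y = 0.034
)

# Whole-proteome composition in the style of the A. thaliana proteome;
# the packaged species background (the species the scan blends toward).
.SPECIES_BG_RAW <- c(
  A = 0.063, C = 0.018, D = 0.054, E = 0.067, F = 0.044,
  G = 0.064, H = 0.023, I = 0.053, K = 0.064, L = 0.095,
  M = 0.024, N = 0.043, P = 0.048, Q = 0.035, R = 0.054,
  S = 0.091, T = 0.051, V = 0.068, W = 0.012, Y = 0.029
)

#' Packaged amino-acid composition tables
#'
#' Returns one of the packaged composition tables, normalized to sum to 1
#' over the 20 canonical amino acids:
#' \describe{
#'   \item{`"prion_foreground"`}{Q/N-rich prion-domain composition (the
#'     scoring foreground).}
#'   \item{`"default_background"`}{yeast-style whole-proteome background.}
#'   \item{`"species_background"`}{Arabidopsis-style whole-proteome
#'     background used as the species term of the alpha blend.}
#' }
#'
#' @param which Table name.
#' @return Named numeric vector over [CANONICAL_AA], summing to 1.
#' @export
#' @examples
#' sum(aa_composition("prion_foreground"))
aa_composition <- function(which = c("prion_foreground",
                                     "default_background",
                                     "species_background")) {
  which <- match.arg(which)
  raw <- switch(which,
    prion_foreground   = .PRION_FG_RAW,
    default_background = .DEFAULT_BG_RAW,
    species_background = .SPECIES_BG_RAW
  )
  .normalize_freqs(raw)
}
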