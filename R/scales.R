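#' Amino-acid scales and alphabets
#'
#' Versioned constant tables used across the annotation pipeline:
#' the Kyte-Doolittle hydropathy scale, a Chou-Fasman-type alpha-helix
#' propensity scale used by the internal helix-block heuristic, and the
#' residue classes (polar, charged, heptad hydrophobics) the motif
#' scanners rely on.
#'
#' @name ecc_scales
#' @keywords internal
NULL

# 20-letter amino-acid alphabet; B/J/O/U/X/Z deliberately rejected upstream.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte & Doolittle (1982) hydropathy values.
KD_SCALE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# Chou-Fasman alpha-helix propensities (P_alpha); > 1 favours helix.
HELIX_PROPENSITY <- c(
  A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13,
  G = 0.57, H = 1.00, I = 1.08, K = 1.16, L = 1.21,
  M = 1.45, N = 0.67, P = 0.57, Q = 1.11, R = 0.98,
  S = 0.77, T = 0.83, V = 1.06, W = 1.08, Y = 0.69
)

# Heptad-interface hydrophobics: coiled coils are defined by L/I/V repeats.
HEPTAD_HYDROPHOBIC <- c("L", "I", "V")

# Polar residues for the Group D 10-residue stretch upstream of EDVID.
POLAR_RESIDUES <- c("S", "T", "N", "Q", "D", "E", "K", "R", "H", "Y")

# "Charged" for the linker charged motif: acidic D/E and basic K/R.
# Histidine is excluded (ambiguous protonation); counted separately on demand.
ACIDIC_RESIDUES <- c("D", "E")
BASIC_RESIDUES  <- c("K", "R")

#' Default thresholds used across the pipeline
#'
#' @return Named list of the pipeline's tunable defaults: `theta_helix`
#'   (smoothed helix-propensity cutoff), `helix_min_len` (minimum block
#'   length), `helix_window` (smoothing window), `theta_polar` (polar
#'   residues of 10 required for the Group D stretch), `theta_charged`
#'   (minimum charged fraction for the linker window to count as the
#'   charged motif), `theta_rpw8`
#'   (percent identity to the CC_R consensus for Group A), `max_mismatch`
#'   (EDVID substitutions allowed), `min_support` (Y2H positive replicates
#'   required of 8), `alpha` and `n_perm` (permutation threshold),
#'   `lod_max` (cap for perfect fits) and `drop` (LOD support interval).
#' @export
#' @examples
#' ecc_defaults()$theta_polar
ecc_defaults <- function() {
  list(
    theta_helix   = 1.03,
    helix_min_len = 6L,
    helix_window  = 7L,
    theta_polar   = 8L,
    theta_charged = 0.5,
    theta_rpw8    = 60,
    max_mismatch  = 0L,
    min_support   = 3L,
    alpha         = 0.05,
    n_perm        = 1000L,
    lod_max       = 50,
    drop          = 1.5
  )
}

#' Synthetic CC_R / RPW8-like signature consensus
#'
#' Group A (CC_R) receptors carry an RPW8-like N-terminal helix
#' arrangement distinct from canonical CNLs. The published consensus is
#' not available as machine-readable sequence, so the package ships a
#' SYNTHETIC 30-residue signature: it is the same string the synthetic
#' panel generator plants at the N-terminus of Group A sequences, and it
#' serves as the default reference profile for the Group A rule in
#' [classify_group()]. Replace it with a consensus built from real CC_R
#' sequences when those are available.
#'
#' @return A single string (30 residues).
#' @export
#' @examples
#' nchar(rpw8_signature())
rpw8_signature <- function() {
  # Helix-rich with heptad L at a/d so it also reads as a coiled coil.
  "LEKQLARMEKQLAKMEQALKEMLKQAEKLM"
}
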