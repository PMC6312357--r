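#' Kyte-Doolittle hydropathy profile
#'
#' Sliding-window mean of Kyte-Doolittle hydropathy values. Only windows
#' fully inside the sequence are reported, so the profile has
#' `nchar(residues) - window + 1` rows; row `i` covers residues
#' `i .. i + window - 1`.
#'
#' @param residues Amino-acid string (or a one-row panel tibble).
#' @param window Odd positive window size (default 3).
#' @return Tibble with columns `start`, `end`, `hydropathy`.
#' @export
#' @examples
#' hydropathy_profile("VVVGGG")
hydropathy_profile <- function(residues, window = 3L) {
  residues <- pull_residues(residues)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("'window' must be an odd positive integer.", call. = FALSE)
  }
  n <- nchar(residues)
  if (window > n) {
    stop("Window (", window, ") exceeds sequence length (", n, ").",
         call. = FALSE)
  }
  vals <- unname(KD_SCALE[strsplit(residues, "")[[1]]])
  means <- sliding_mean(vals, window)
  tibble::tibble(
    start = seq_len(n - window + 1L),
    end = seq_len(n - window + 1L) + window - 1L,
    hydropathy = means
  )
}

# Mean over fully-interior windows; length(x) - w + 1 values.
sliding_mean <- function(x, w) {
  cs <- cumsum(c(0, x))
  (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
}

# Accept either a bare residue string or a one-row panel tibble.
pull_residues <- function(x) {
  if (is.character(x) && length(x) == 1L) return(x)
  if (is.data.frame(x) && "residues" %in% names(x) && nrow(x) == 1L) {
    return(x$residues)
  }
  stop("Expected a single residue string or a one-row panel tibble.",
       call. = FALSE)
}
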