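#' Predict alpha-helix blocks
#'
#' Internal heuristic standing in for a consensus of secondary-structure
#' predictors: per-residue Chou-Fasman helix propensities are smoothed
#' with a centered window (shrinking at the edges so every residue gets a
#' value) and maximal runs above `theta` of at least `min_len` residues
#' become helix blocks. A user-supplied per-residue track overrides the
#' heuristic entirely: a logical vector marks helical residues, a numeric
#' vector is thresholded at `theta`.
#'
#' Blocks are labelled in N-to-C order: with four or more blocks the
#' first four are H1a, H1b, H2a, H2b (extras `other`); with three the
#' first is taken as a merged H1 (the H1a/H1b separation is often not
#' resolved) followed by H2a, H2b; with fewer, H1 then H2a.
#'
#' @param residues Amino-acid string (or one-row panel tibble).
#' @param track Optional per-residue override (logical or numeric, same
#'   length as the sequence).
#' @param theta Propensity threshold (default `ecc_defaults()$theta_helix`).
#' @param window Smoothing window (odd; default 7).
#' @param min_len Minimum block length for the heuristic (default 6).
#' @return Tibble with columns `label`, `start`, `end`; zero rows when no
#'   block is found (a candidate Group E architecture).
#' @export
#' @examples
#' predict_helix_blocks(strrep("P", 10) %+% strrep("A", 30) %+% strrep("P", 10))
predict_helix_blocks <- function(residues, track = NULL,
                                 theta = ecc_defaults()$theta_helix,
                                 window = ecc_defaults()$helix_window,
                                 min_len = ecc_defaults()$helix_min_len) {
  residues <- pull_residues(residues)
  n <- nchar(residues)
  if (!is.null(track)) {
    if (length(track) != n) {
      stop("Helix track length (", length(track),
           ") must equal sequence length (", n, ").", call. = FALSE)
    }
    helical <- if (is.logical(track)) track else track >= theta
    spans <- runs_to_spans(helical, min_len = 1L)
  } else {
    prop <- HELIX_PROPENSITY[strsplit(residues, "")[[1]]]
    sm <- centered_mean(prop, window)
    spans <- runs_to_spans(sm > theta, min_len = min_len)
  }
  label_helices(spans)
}

# Centered moving average with edge windows truncated to the sequence.
centered_mean <- function(x, w) {
  half <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

runs_to_spans <- function(flag, min_len) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  tibble::tibble(start = starts[keep], end = ends[keep])
}

label_helices <- function(spans) {
  k <- nrow(spans)
  labels <- if (k == 0L) {
    character()
  } else if (k >= 4L) {
    c("H1a", "H1b", "H2a", "H2b", rep("other", k - 4L))
  } else if (k == 3L) {
    c("H1", "H2a", "H2b")
  } else if (k == 2L) {
    c("H1", "H2a")
  } else {
    "H1"
  }
  tibble::tibble(label = labels, start = spans$start, end = spans$end)
}

#' Assign the coiled-coil heptad register
#'
#' Within each helix block the frame (of seven) that maximizes the count
#' of heptad hydrophobics (L/I/V) at `a` and `d` positions is chosen;
#' ties go to the smaller frame offset. Residues inside helices get the
#' letters `a`-`g`; everything else gets `.`.
#'
#' @param residues Amino-acid string (or one-row panel tibble).
#' @param helices Helix-span tibble from [predict_helix_blocks()].
#' @return A register string of the same length as the sequence.
#' @export
assign_heptad_register <- function(residues, helices) {
  residues <- pull_residues(residues)
  n <- nchar(residues)
  chars <- strsplit(residues, "")[[1]]
  reg <- rep(".", n)
  letters7 <- letters[1:7]
  for (i in seq_len(nrow(helices))) {
    idx <- helices$start[i]:helices$end[i]
    best <- best_heptad_frame(chars[idx])
    pos_in_helix <- seq_along(idx) - 1L
    reg[idx] <- letters7[((pos_in_helix + best) %% 7L) + 1L]
  }
  paste(reg, collapse = "")
}

# Frame f means the first helix residue is heptad position (f mod 7) -> a=0.
best_heptad_frame <- function(chars) {
  hydro <- chars %in% HEPTAD_HYDROPHOBIC
  pos <- seq_along(chars) - 1L
  counts <- vapply(0:6, function(f) {
    hept <- (pos + f) %% 7L
    sum(hydro & (hept == 0L | hept == 3L))
  }, integer(1))
  which.max(counts) - 1L  # ties -> smallest frame
}

#' @rdname grapes-plus-grapes
#' @name %+%
#' @title String concatenation helper
#' @param lhs,rhs Strings.
#' @return `paste0(lhs, rhs)`.
#' @export
`%+%` <- function(lhs, rhs) paste0(lhs, rhs)
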