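#' Motif scanners for ECC annotation
#'
#' Each scanner returns a one-row tibble
#' (`name`, `start`, `end`, `mismatches`, `matched_text`) or `NULL` when
#' the motif is absent. Coordinates are 1-based inclusive with the
#' initiator Met at position 1.
#'
#' @name ecc_motifs
NULL

motif_hit <- function(name, start, residues, len, mismatches = 0L) {
  end <- start + len - 1L
  tibble::tibble(
    name = name, start = as.integer(start), end = as.integer(end),
    mismatches = as.integer(mismatches),
    matched_text = substr(residues, start, end)
  )
}

#' Find the EDVID motif
#'
#' Best (fewest mismatches, then leftmost) occurrence of the five-residue
#' EDVID motif, allowing up to `max_mismatch` substitutions. Exact by
#' default: the motif is sharply conserved only in Groups C and D.
#'
#' @param residues Amino-acid string (or one-row panel tibble).
#' @param max_mismatch Substitutions tolerated (default 0).
#' @return One-row motif tibble or `NULL`.
#' @export
#' @examples
#' find_edvid("MAAEDVIDAA")
find_edvid <- function(residues, max_mismatch = ecc_defaults()$max_mismatch) {
  residues <- pull_residues(residues)
  pattern <- c("E", "D", "V", "I", "D")
  n <- nchar(residues)
  if (n < 5L) return(NULL)
  chars <- strsplit(residues, "")[[1]]
  best_start <- NA_integer_
  best_mm <- max_mismatch + 1L
  for (s in 1:(n - 4L)) {
    mm <- sum(chars[s:(s + 4L)] != pattern)
    if (mm < best_mm) {
      best_mm <- mm
      best_start <- s
      if (mm == 0L) break
    }
  }
  if (best_mm > max_mismatch) return(NULL)
  motif_hit("EDVID", best_start, residues, 5L, best_mm)
}

#' Find the Group D polar stretch
#'
#' Examines the 10 residues immediately upstream of an EDVID hit; a hit
#' is reported iff at least `theta_polar` of the 10 are polar
#' (S/T/N/Q/D/E/K/R/H/Y). The span is exactly those 10 residues.
#'
#' @param residues Amino-acid string (or one-row panel tibble).
#' @param edvid One-row motif tibble from [find_edvid()].
#' @param theta_polar Minimum polar count of 10 (default 8).
#' @return One-row motif tibble or `NULL` (also when fewer than 10
#'   residues precede EDVID).
#' @export
find_polar_stretch <- function(residues, edvid,
                               theta_polar = ecc_defaults()$theta_polar) {
  residues <- pull_residues(residues)
  if (is.null(edvid)) stop("'edvid' hit is required.", call. = FALSE)
  start <- edvid$start - 10L
  if (start < 1L) return(NULL)
  window <- strsplit(substr(residues, start, edvid$start - 1L), "")[[1]]
  n_polar <- sum(window %in% POLAR_RESIDUES)
  if (n_polar < theta_polar) return(NULL)
  motif_hit("polar_stretch", start, residues, 10L,
            mismatches = 10L - n_polar)
}

#' Find the pre-P-loop motif
#'
#' Leftmost match of the 15-residue CNL pre-P-loop consensus
#' `[VI] G x8 [LI] x3 L`. The reported `vg` position is the position of
#' the V/I of the conserved VG dipeptide (= `start`).
#'
#' @param residues Amino-acid string (or one-row panel tibble).
#' @return One-row motif tibble with an extra `vg` column, or `NULL`.
#' @export
#' @examples
#' find_preploop("AAVGAAAAAAAAIAAAL")
find_preploop <- function(residues) {
  residues <- pull_residues(residues)
  m <- regexpr("[VI]G.{8}[LI].{3}L", residues)
  if (m == -1L) return(NULL)
  hit <- motif_hit("preploop", as.integer(m), residues, 15L)
  hit$vg <- hit$start
  hit
}

#' Find the Walker-A P-loop
#'
#' Leftmost match of the Walker-A pattern `G x4 G K [ST]` occurring after
#' the pre-P-loop hit (when one exists). The ECC boundary is defined as
#' `ploop start - 1`; when no P-loop is found the boundary falls back to
#' the sequence end.
#'
#' @param residues Amino-acid string (or one-row panel tibble).
#' @param preploop Optional pre-P-loop hit from [find_preploop()]; when
#'   supplied only matches starting after its `start` are considered.
#' @param pattern Walker-A regular expression (configurable; default the
#'   canonical `G.{4}GK[ST]`, 8 residues).
#' @return One-row motif tibble or `NULL`.
#' @export
find_ploop <- function(residues, preploop = NULL, pattern = "G.{4}GK[ST]") {
  residues <- pull_residues(residues)
  from <- if (!is.null(preploop)) preploop$start + 1L else 1L
  tail_str <- substr(residues, from, nchar(residues))
  m <- regexpr(pattern, tail_str)
  if (m == -1L) return(NULL)
  motif_hit("ploop", as.integer(m) + from - 1L, residues,
            attr(m, "match.length"))
}

#' Locate the charged linker motif
#'
#' The cluster of charged residues in the CC-NB linker occupies positions
#' -11 to -3 relative to the V of the conserved VG dipeptide of the
#' pre-P-loop (a 9-residue window, both ends inclusive). Counts acidic
#' (D/E) and basic (K/R) residues; histidine is excluded from "charged".
#'
#' @param residues Amino-acid string (or one-row panel tibble).
#' @param vg_position Position of the V/I of the VG dipeptide.
#' @return One-row tibble `start`, `end`, `n_acidic`, `n_basic`,
#'   `charged_fraction`, `matched_text`.
#' @export
#' @examples
#' locate_charged_motif(strrep("A", 88) %+% "EEDKRDEKE" %+% "AAVG", 100)
locate_charged_motif <- function(residues, vg_position) {
  residues <- pull_residues(residues)
  start <- vg_position - 11L
  end <- vg_position - 3L
  if (start < 1L) {
    stop("Charged-motif window out of range: needs ", 1L - start,
         " residue(s) before position 1 (VG at ", vg_position, ").",
         call. = FALSE)
  }
  window <- strsplit(substr(residues, start, end), "")[[1]]
  n_ac <- sum(window %in% ACIDIC_RESIDUES)
  n_ba <- sum(window %in% BASIC_RESIDUES)
  tibble::tibble(
    start = as.integer(start), end = as.integer(end),
    n_acidic = n_ac, n_basic = n_ba,
    charged_fraction = (n_ac + n_ba) / length(window),
    matched_text = substr(residues, start, end)
  )
}

#' Find CC-END
#'
#' CC-END is the last heptad-interface hydrophobic residue of the CC
#' domain: the largest index within the last helix (H2b when labelled)
#' whose residue is L/I/V and whose register letter is `a` or `d`.
#'
#' @param residues Amino-acid string (or one-row panel tibble).
#' @param register Register string from [assign_heptad_register()].
#' @param helices Helix tibble from [predict_helix_blocks()].
#' @return Integer position, or `NULL` when no such residue exists.
#' @export
find_cc_end <- function(residues, register, helices) {
  residues <- pull_residues(residues)
  if (nrow(helices) == 0L) return(NULL)
  h <- if ("H2b" %in% helices$label) {
    helices[helices$label == "H2b", ][1, ]
  } else {
    helices[nrow(helices), ]
  }
  idx <- h$start:h$end
  chars <- strsplit(residues, "")[[1]][idx]
  reg <- strsplit(register, "")[[1]][idx]
  ok <- chars %in% HEPTAD_HYDROPHOBIC & reg %in% c("a", "d")
  if (!any(ok)) return(NULL)
  as.integer(max(idx[ok]))
}

#' Extract the CCVX segment
#'
#' CCVX is the variable stretch between CC-END and the charged motif:
#' `[cc_end + 1, charged$start - 1]`. Canonical CCVX segments are 16-18
#' residues; other lengths are flagged, not rejected.
#'
#' @param residues Amino-acid string (or one-row panel tibble).
#' @param cc_end CC-END position from [find_cc_end()].
#' @param charged Charged-motif tibble from [locate_charged_motif()].
#' @return One-row tibble `start`, `end`, `length`, `canonical`.
#' @export
extract_ccvx <- function(residues, cc_end, charged) {
  residues <- pull_residues(residues)
  if (cc_end >= charged$start) {
    stop("CC-END (", cc_end, ") must precede the charged motif (starts ",
         charged$start, ").", call. = FALSE)
  }
  start <- cc_end + 1L
  end <- charged$start - 1L
  len <- end - start + 1L
  tibble::tibble(
    start = as.integer(start), end = as.integer(end),
    length = as.integer(len),
    canonical = len >= 16L && len <= 18L
  )
}

#' Detect N-terminal acylation motifs
#'
#' Myristoylation requires Gly at positions 2 and 3; palmitoylation a
#' Cys or Ser at position 4 (the Group B "MGG C/S" start).
#'
#' @param residues Amino-acid string (or one-row panel tibble).
#' @return Tibble with logical columns `myristoylation`, `palmitoylation`.
#' @export
#' @examples
#' detect_acylation("MGGCSAAA")
detect_acylation <- function(residues) {
  residues <- pull_residues(residues)
  if (nchar(residues) < 4L) {
    stop("Sequence shorter than 4 residues.", call. = FALSE)
  }
  tibble::tibble(
    myristoylation = substr(residues, 2, 3) == "GG",
    palmitoylation = substr(residues, 4, 4) %in% c("C", "S")
  )
}
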