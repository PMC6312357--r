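#' Breakpoint anchor for chimera construction
#'
#' The swap series uses three feature-defined breakpoints: `CC_END`
#' (the last heptad hydrophobic of H2b), `CHARGED` (the first acidic
#' residue, E or D, within the charged-motif window -- the "E or EE"
#' residues of the charged island) and `VG` (the V of the pre-P-loop VG
#' dipeptide).
#'
#' @param annotation An `ecc_annotation`.
#' @param breakpoint One of `"CC_END"`, `"CHARGED"`, `"VG"`.
#' @return Integer residue position of the anchor.
#' @export
breakpoint_anchor <- function(annotation,
                              breakpoint = c("CC_END", "CHARGED", "VG")) {
  breakpoint <- match.arg(breakpoint)
  fail <- function(what) {
    stop("Parent '", annotation$id, "' lacks the ", what,
         " feature needed for breakpoint ", breakpoint, ".", call. = FALSE)
  }
  if (breakpoint == "CC_END") {
    if (is.null(annotation$cc_end)) fail("CC-END")
    annotation$cc_end
  } else if (breakpoint == "VG") {
    if (is.null(annotation$preploop)) fail("pre-P-loop")
    annotation$preploop$vg
  } else {
    if (is.null(annotation$charged)) fail("charged-motif")
    window <- strsplit(annotation$charged$matched_text, "")[[1]]
    acidic <- which(window %in% ACIDIC_RESIDUES)
    if (length(acidic) == 0L) fail("acidic residue within the charged")
    annotation$charged$start + acidic[1] - 1L
  }
}

#' Reciprocal swap of two ECCs at a feature breakpoint
#'
#' Builds both chimeras: `ab` carries parent A up to and including the
#' breakpoint anchor, then parent B from the residue after its own
#' anchor (and `ba` reciprocally). Chimeras should be re-annotated; the
#' pipeline never trusts parental coordinates on a chimera.
#'
#' @param parent_a,parent_b `ecc_annotation` objects.
#' @param breakpoint `"CC_END"`, `"CHARGED"` or `"VG"`.
#' @param label Clone label appended to the chimera ids (e.g. "A1").
#' @return Two-row panel tibble (`id`, `residues`, `description`) with
#'   the `ab` and `ba` chimeras.
#' @export
swap_at_breakpoint <- function(parent_a, parent_b,
                               breakpoint = c("CC_END", "CHARGED", "VG"),
                               label = breakpoint[1]) {
  breakpoint <- match.arg(breakpoint)
  bp_a <- breakpoint_anchor(parent_a, breakpoint)
  bp_b <- breakpoint_anchor(parent_b, breakpoint)
  ra <- parent_a$residues
  rb <- parent_b$residues
  ab <- substr(ra, 1, bp_a) %+% substr(rb, bp_b + 1L, nchar(rb))
  ba <- substr(rb, 1, bp_b) %+% substr(ra, bp_a + 1L, nchar(ra))
  tibble::tibble(
    id = paste0(c(parent_a$id, parent_b$id), "_", label,
                c("_ab", "_ba")),
    residues = c(ab, ba),
    description = paste0("chimera at ", breakpoint, " of ",
                         c(paste0(parent_a$id, "/", parent_b$id),
                           paste0(parent_b$id, "/", parent_a$id)))
  )
}

#' Delete a segment from an ECC
#'
#' Excises the residues of a named feature (`"charged"`, `"ccvx"`,
#' `"edvid"`, `"polar_stretch"`) or an explicit `[start, end]` span. An
#' empty span (`end < start`) is the identity.
#'
#' @param annotation An `ecc_annotation`.
#' @param segment Feature name or integer `c(start, end)`.
#' @return One-row panel tibble with the deletion clone.
#' @export
delete_segment <- function(annotation, segment) {
  res <- annotation$residues
  n <- nchar(res)
  if (is.character(segment)) {
    span <- switch(segment,
      charged = c(annotation$charged$start, annotation$charged$end),
      ccvx = c(annotation$ccvx$start, annotation$ccvx$end),
      edvid = c(annotation$edvid$start, annotation$edvid$end),
      polar_stretch = c(annotation$polar_stretch$start,
                        annotation$polar_stretch$end),
      stop("Unknown segment name '", segment, "'.", call. = FALSE))
    if (length(span) == 0L || is.null(span)) {
      stop("Feature '", segment, "' is absent from '", annotation$id,
           "'.", call. = FALSE)
    }
  } else {
    span <- as.integer(segment)
  }
  if (span[2] < span[1]) {  # empty segment: identity
    return(tibble::tibble(id = annotation$id, residues = res,
                          description = "no-op deletion"))
  }
  if (span[1] < 1L || span[2] > n) {
    stop("Segment [", span[1], ",", span[2], "] out of range 1..", n, ".",
         call. = FALSE)
  }
  out <- substr(res, 1, span[1] - 1L) %+% substr(res, span[2] + 1L, n)
  tibble::tibble(
    id = paste0(annotation$id, "_del", span[1], "_", span[2]),
    residues = out,
    description = paste0("deletion of [", span[1], ",", span[2], "]")
  )
}

#' Apply point mutations to an ECC
#'
#' Each mutation states the expected parental residue; a mismatch is an
#' error (guards against coordinate drift between clone generations).
#'
#' @param annotation An `ecc_annotation`.
#' @param mutations Tibble (or data frame) with columns `position`,
#'   `from_res`, `to_res`.
#' @return One-row panel tibble with the mutant.
#' @export
#' @examples
#' ann <- annotate_ecc("MAAEEGAA")
#' apply_point_mutations(ann, tibble::tibble(position = 4:5,
#'   from_res = "E", to_res = "K"))
apply_point_mutations <- function(annotation, mutations) {
  res <- annotation$residues
  chars <- strsplit(res, "")[[1]]
  mutations <- tibble::as_tibble(mutations)
  for (i in seq_len(nrow(mutations))) {
    p <- mutations$position[i]
    if (p < 1L || p > length(chars)) {
      stop("Mutation position ", p, " out of range.", call. = FALSE)
    }
    if (chars[p] != mutations$from_res[i]) {
      stop("Mutation ", mutations$from_res[i], p, mutations$to_res[i],
           ": parent has '", chars[p], "' at position ", p,
           ", not '", mutations$from_res[i], "'.", call. = FALSE)
    }
    chars[p] <- mutations$to_res[i]
  }
  lab <- if (nrow(mutations) == 0L) "" else
    paste0("_", paste0(mutations$from_res, mutations$position,
                       mutations$to_res, collapse = "_"))
  tibble::tibble(
    id = paste0(annotation$id, lab),
    residues = paste(chars, collapse = ""),
    description = if (nrow(mutations) == 0L) "no mutations" else
      paste(nrow(mutations), "point mutation(s)")
  )
}
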