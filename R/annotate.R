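#' Annotate one ECC sequence
#'
#' Runs every feature finder in dependency order and composes the full
#' ECC annotation: hydropathy profile, helix blocks, heptad register,
#' EDVID and the Group D polar stretch, N-terminal acylation motifs, the
#' pre-P-loop and Walker-A P-loop, the charged linker motif (-11..-3 of
#' VG), CC-END and the CCVX segment. Absent features are recorded as
#' absent, never fabricated; the ECC boundary is the residue before the
#' P-loop (sequence end when no P-loop is found).
#'
#' @param record One-row panel tibble (columns `id`, `residues`) or a
#'   bare residue string.
#' @param track Optional per-residue helix track (see
#'   [predict_helix_blocks()]).
#' @param max_mismatch EDVID mismatch tolerance (default 0).
#' @param theta_polar Polar-stretch threshold (default 8 of 10).
#' @param theta_charged Minimum charged fraction for the -11..-3 window
#'   to be reported as the charged motif (default 0.5): the window
#'   always exists upstream of a located VG, but the motif is only
#'   called when the cluster is actually charged, so deletion clones
#'   re-annotate as charged-absent.
#' @return An `ecc_annotation` object; see [tidy.ecc_annotation()] for
#'   the flat feature table.
#' @export
#' @examples
#' ann <- annotate_ecc(gen_ecc_panel(panel_spec(n_d = 1), seed = 1)$panel)
#' tidy(ann)
annotate_ecc <- function(record, track = NULL,
                         max_mismatch = ecc_defaults()$max_mismatch,
                         theta_polar = ecc_defaults()$theta_polar,
                         theta_charged = ecc_defaults()$theta_charged) {
  if (is.character(record) && length(record) == 1L) {
    record <- tibble::tibble(id = "seq1", residues = record,
                             description = "")
  }
  record <- as_panel(record)
  if (nrow(record) != 1L) {
    stop("annotate_ecc() takes exactly one record; see annotate_panel().",
         call. = FALSE)
  }
  validate_panel(record)
  residues <- record$residues
  n <- nchar(residues)

  helices <- predict_helix_blocks(residues, track = track)
  register <- assign_heptad_register(residues, helices)
  edvid <- find_edvid(residues, max_mismatch = max_mismatch)
  polar <- if (!is.null(edvid)) {
    find_polar_stretch(residues, edvid, theta_polar = theta_polar)
  } else NULL
  acyl <- if (n >= 4L) detect_acylation(residues) else {
    tibble::tibble(myristoylation = FALSE, palmitoylation = FALSE)
  }
  preploop <- find_preploop(residues)
  ploop <- find_ploop(residues, preploop = preploop)
  charged <- NULL
  if (!is.null(preploop) && preploop$vg - 11L >= 1L) {
    charged <- locate_charged_motif(residues, preploop$vg)
    if (charged$charged_fraction < theta_charged) charged <- NULL
  }
  cc_end <- find_cc_end(residues, register, helices)
  ccvx <- NULL
  if (!is.null(cc_end) && !is.null(charged) && cc_end < charged$start) {
    ccvx <- extract_ccvx(residues, cc_end, charged)
  }
  boundary <- if (!is.null(ploop)) ploop$start - 1L else n

  ann <- structure(
    list(
      id = record$id, residues = residues,
      helices = helices, register = register,
      edvid = edvid, polar_stretch = polar, acylation = acyl,
      preploop = preploop, ploop = ploop, charged = charged,
      cc_end = cc_end, ccvx = ccvx,
      ecc_boundary = as.integer(boundary),
      group = NA_character_
    ),
    class = "ecc_annotation"
  )
  assert_feature_order(ann)
  ann
}

# Feature order along the sequence: helices < cc_end < ccvx < charged <
# preploop VG < ploop; asserted on every annotation the pipeline emits.
assert_feature_order <- function(ann) {
  ok <- TRUE
  if (!is.null(ann$cc_end) && nrow(ann$helices) > 0L) {
    ok <- ok && ann$cc_end <= max(ann$helices$end)
  }
  if (!is.null(ann$cc_end) && !is.null(ann$ccvx)) {
    ok <- ok && ann$cc_end < ann$ccvx$start
  }
  if (!is.null(ann$ccvx) && !is.null(ann$charged)) {
    ok <- ok && ann$ccvx$end == ann$charged$start - 1L
  }
  if (!is.null(ann$charged) && !is.null(ann$preploop)) {
    ok <- ok && ann$charged$end < ann$preploop$vg
  }
  if (!is.null(ann$ploop)) {
    ok <- ok && ann$ecc_boundary < ann$ploop$start
    if (!is.null(ann$preploop)) ok <- ok && ann$preploop$vg < ann$ploop$start
  }
  if (!ok) {
    stop("Internal error: feature-order invariant violated for '",
         ann$id, "'.", call. = FALSE)
  }
  invisible(ann)
}

#' @export
print.ecc_annotation <- function(x, ...) {
  cat("<ecc_annotation> ", x$id, " (", nchar(x$residues), " aa)\n", sep = "")
  cat("  helices: ", nrow(x$helices),
      if (nrow(x$helices) > 0)
        paste0(" [", paste(x$helices$label, collapse = ", "), "]") else "",
      "\n", sep = "")
  cat("  EDVID: ", if (is.null(x$edvid)) "absent" else x$edvid$start,
      "; polar stretch: ",
      if (is.null(x$polar_stretch)) "absent" else x$polar_stretch$start,
      "\n", sep = "")
  cat("  pre-P-loop VG: ",
      if (is.null(x$preploop)) "absent" else x$preploop$vg,
      "; P-loop: ", if (is.null(x$ploop)) "absent" else x$ploop$start,
      "; ECC boundary: ", x$ecc_boundary, "\n", sep = "")
  cat("  CC-END: ", if (is.null(x$cc_end)) "absent" else x$cc_end,
      "; CCVX: ",
      if (is.null(x$ccvx)) "absent"
      else paste0("[", x$ccvx$start, ",", x$ccvx$end, "] (", x$ccvx$length,
                  " aa", if (!x$ccvx$canonical) ", non-canonical", ")"),
      "\n", sep = "")
  if (!is.na(x$group)) cat("  group: ", x$group, "\n", sep = "")
  invisible(x)
}

#' Tidy an ECC annotation into a feature table
#'
#' @param x An `ecc_annotation`.
#' @param ... Unused.
#' @return Tibble with columns `id`, `feature`, `start`, `end`, `detail`
#'   (one row per located feature, 1-based inclusive coordinates).
#' @export
tidy.ecc_annotation <- function(x, ...) {
  rows <- list()
  add <- function(feature, start, end, detail = "") {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      id = x$id, feature = feature,
      start = as.integer(start), end = as.integer(end), detail = detail)
  }
  for (i in seq_len(nrow(x$helices))) {
    add("helix", x$helices$start[i], x$helices$end[i], x$helices$label[i])
  }
  if (!is.null(x$edvid)) add("EDVID", x$edvid$start, x$edvid$end,
                             x$edvid$matched_text)
  if (!is.null(x$polar_stretch)) {
    add("polar_stretch", x$polar_stretch$start, x$polar_stretch$end,
        x$polar_stretch$matched_text)
  }
  if (x$acylation$myristoylation) add("myristoylation", 2L, 3L, "GG")
  if (x$acylation$palmitoylation) {
    add("palmitoylation", 4L, 4L, substr(x$residues, 4, 4))
  }
  if (!is.null(x$cc_end)) add("CC_END", x$cc_end, x$cc_end,
                              substr(x$residues, x$cc_end, x$cc_end))
  if (!is.null(x$ccvx)) {
    add("CCVX", x$ccvx$start, x$ccvx$end,
        if (x$ccvx$canonical) "canonical" else "non-canonical")
  }
  if (!is.null(x$charged)) {
    add("charged_motif", x$charged$start, x$charged$end,
        sprintf("acidic=%d;basic=%d", x$charged$n_acidic,
                x$charged$n_basic))
  }
  if (!is.null(x$preploop)) add("preploop", x$preploop$start,
                                x$preploop$end, x$preploop$matched_text)
  if (!is.null(x$ploop)) add("ploop", x$ploop$start, x$ploop$end,
                             x$ploop$matched_text)
  add("ECC", 1L, x$ecc_boundary, "N-terminus up to the P-loop")
  dplyr::bind_rows(rows)
}

#' One-row summary of an ECC annotation
#' @param x An `ecc_annotation`.
#' @param ... Unused.
#' @return One-row tibble of presence flags and key coordinates.
#' @export
glance.ecc_annotation <- function(x, ...) {
  tibble::tibble(
    id = x$id,
    length = nchar(x$residues),
    n_helices = nrow(x$helices),
    edvid = !is.null(x$edvid),
    polar_stretch = !is.null(x$polar_stretch),
    myristoylation = x$acylation$myristoylation,
    palmitoylation = x$acylation$palmitoylation,
    cc_end = if (is.null(x$cc_end)) NA_integer_ else x$cc_end,
    ccvx_length = if (is.null(x$ccvx)) NA_integer_ else x$ccvx$length,
    charged_fraction = if (is.null(x$charged)) NA_real_
                       else x$charged$charged_fraction,
    vg = if (is.null(x$preploop)) NA_integer_ else x$preploop$vg,
    ploop_start = if (is.null(x$ploop)) NA_integer_ else x$ploop$start,
    ecc_boundary = x$ecc_boundary,
    group = x$group
  )
}

#' Annotate a whole sequence panel
#'
#' @param panel Panel tibble from [read_fasta()] or [gen_ecc_panel()].
#' @inheritParams annotate_ecc
#' @return Tibble with one row per sequence: the [glance.ecc_annotation()]
#'   summary columns plus a list-column `annotation` holding the full
#'   `ecc_annotation` objects.
#' @export
annotate_panel <- function(panel, max_mismatch = ecc_defaults()$max_mismatch,
                           theta_polar = ecc_defaults()$theta_polar,
                           theta_charged = ecc_defaults()$theta_charged) {
  panel <- as_panel(panel)
  anns <- purrr::map(seq_len(nrow(panel)), function(i) {
    annotate_ecc(panel[i, ], max_mismatch = max_mismatch,
                 theta_polar = theta_polar, theta_charged = theta_charged)
  })
  out <- dplyr::bind_rows(purrr::map(anns, glance))
  out$annotation <- anns
  out
}

#' Export annotations as GFF3 (protein coordinates)
#'
#' Writes one GFF3 feature line per located feature, 1-based inclusive,
#' with the sequence id as the landmark. Feature types follow the ECC
#' vocabulary (`ECC_helix`, `EDVID`, `preploop`, `ploop`,
#' `charged_motif`, `CCVX`, ...).
#'
#' @param annotated Output of [annotate_panel()] (or a single
#'   `ecc_annotation`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotated, path) {
  feats <- annotation_features(annotated)
  type_map <- c(
    helix = "ECC_helix", EDVID = "EDVID", polar_stretch = "polar_stretch",
    myristoylation = "myristoylation", palmitoylation = "palmitoylation",
    CC_END = "CC_END", CCVX = "CCVX", charged_motif = "charged_motif",
    preploop = "preploop", ploop = "ploop", ECC = "ECC"
  )
  gr <- GenomicRanges::GRanges(
    seqnames = feats$id,
    ranges = IRanges::IRanges(start = feats$start, end = feats$end),
    type = unname(type_map[feats$feature]),
    source = "ecckit",
    Note = feats$detail
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Export annotations as a flat TSV
#' @inheritParams write_annotation_gff3
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annotated, path) {
  readr::write_tsv(annotation_features(annotated), path)
  invisible(path)
}

annotation_features <- function(annotated) {
  if (inherits(annotated, "ecc_annotation")) return(tidy(annotated))
  if (is.data.frame(annotated) && "annotation" %in% names(annotated)) {
    return(dplyr::bind_rows(purrr::map(annotated$annotation, tidy)))
  }
  stop("Expected an ecc_annotation or the output of annotate_panel().",
       call. = FALSE)
}

#' Feature map of an annotated ECC
#'
#' Draws the located features as horizontal segments over the residue
#' axis, with the Kyte-Doolittle window-3 hydropathy profile underneath.
#'
#' @param object An `ecc_annotation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecc_annotation <- function(object, ...) {
  feats <- tidy(object)
  feats <- feats[feats$feature != "ECC", ]
  hp <- hydropathy_profile(object$residues)
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = hp,
      ggplot2::aes(x = (.data$start + .data$end) / 2,
                   y = .data$hydropathy / max(abs(.data$hydropathy)) - 2),
      colour = "grey50") +
    ggplot2::geom_segment(
      data = feats,
      ggplot2::aes(x = .data$start - 0.45, xend = .data$end + 0.45,
                   y = .data$feature, yend = .data$feature,
                   colour = .data$feature),
      linewidth = 4, show.legend = FALSE) +
    ggplot2::labs(x = "residue (1-based)", y = NULL,
                  title = object$id,
                  subtitle = "feature map; scaled hydropathy below") +
    ggplot2::theme_minimal()
}
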