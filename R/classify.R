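#' Classify an annotated ECC into Groups A-E
#'
#' Decision cascade over the annotated architecture:
#' 1. no helix block (no coiled-coil evidence) -> `E`;
#' 2. percent identity of the CC_R/RPW8-like consensus against the
#'    N-terminal region at or above `theta_rpw8` -> `A`;
#' 3. EDVID present together with the 10-polar upstream stretch -> `D`;
#' 4. EDVID present -> `C`;
#' 5. otherwise -> `B`.
#' The evidence map records every rule outcome, including the
#' acylation flags typical of Group B (recorded as evidence, not
#' required by the cascade).
#'
#' @param annotation An `ecc_annotation`.
#' @param rpw8 Reference CC_R consensus string (default the shipped
#'   synthetic [rpw8_signature()]).
#' @param theta_rpw8 Percent-identity threshold for the Group A rule
#'   (default 60).
#' @return One-row tibble: `id`, `group` and logical evidence columns
#'   `cc_detected`, `rpw8_signature`, `edvid_present`, `polar_stretch`,
#'   `acylation`, plus `rpw8_identity`.
#' @export
classify_group <- function(annotation, rpw8 = rpw8_signature(),
                           theta_rpw8 = ecc_defaults()$theta_rpw8) {
  stopifnot(inherits(annotation, "ecc_annotation"))
  cc_detected <- nrow(annotation$helices) > 0L
  pid <- rpw8_identity(annotation$residues, rpw8)
  is_rpw8 <- cc_detected && pid >= theta_rpw8
  edvid <- !is.null(annotation$edvid)
  polar <- !is.null(annotation$polar_stretch)
  acyl <- annotation$acylation$myristoylation &&
    annotation$acylation$palmitoylation
  group <- if (!cc_detected) "E"
           else if (is_rpw8) "A"
           else if (edvid && polar) "D"
           else if (edvid) "C"
           else "B"
  tibble::tibble(
    id = annotation$id, group = group,
    cc_detected = cc_detected, rpw8_signature = is_rpw8,
    edvid_present = edvid, polar_stretch = polar, acylation = acyl,
    rpw8_identity = pid
  )
}

# Percent identity of the consensus aligned (global in the consensus,
# local in the target) against the sequence N-terminus.
rpw8_identity <- function(residues, rpw8) {
  prefix <- substr(residues, 1, min(nchar(residues),
                                    nchar(rpw8) + 15L))
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(rpw8),
    subject = Biostrings::AAString(prefix),
    type = "global-local",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 4)
  Biostrings::pid(aln, type = "PID1")
}

#' Classify every sequence of an annotated panel
#'
#' @param annotated Output of [annotate_panel()].
#' @inheritParams classify_group
#' @return The input tibble with the classification columns joined and
#'   `group` filled in (annotation objects updated too).
#' @export
classify_panel <- function(annotated, rpw8 = rpw8_signature(),
                           theta_rpw8 = ecc_defaults()$theta_rpw8) {
  calls <- dplyr::bind_rows(purrr::map(
    annotated$annotation, classify_group,
    rpw8 = rpw8, theta_rpw8 = theta_rpw8))
  annotated$group <- calls$group
  annotated$annotation <- purrr::map2(annotated$annotation, calls$group,
                                      function(a, g) { a$group <- g; a })
  attr(annotated, "evidence") <- calls
  annotated
}

#' Percent identity and similarity between two aligned rows
#'
#' Columns where both rows are gaps are excluded. Identity is the
#' percentage of remaining columns with identical residues; similarity
#' additionally counts columns whose substitution-matrix score is
#' positive (BLOSUM62 by default, so similarity >= identity).
#'
#' @param row_a,row_b Aligned strings of equal length (gap `-`).
#' @param matrix Substitution matrix name (default "BLOSUM62").
#' @return One-row tibble `identity`, `similarity` (percent), `columns`.
#' @export
#' @examples
#' pairwise_identity_similarity("ACDE", "ACDF")
pairwise_identity_similarity <- function(row_a, row_b,
                                         matrix = "BLOSUM62") {
  if (nchar(row_a) != nchar(row_b)) {
    stop("Aligned rows must have equal length.", call. = FALSE)
  }
  a <- strsplit(row_a, "")[[1]]
  b <- strsplit(row_b, "")[[1]]
  keep <- !(a == "-" & b == "-")
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n == 0L) stop("Alignment has no non-gap columns.", call. = FALSE)
  ident <- a == b & a != "-"
  subst <- getAAMatrix(matrix)
  both_res <- a != "-" & b != "-"
  pos_score <- rep(FALSE, n)
  pos_score[both_res] <- subst[cbind(a[both_res], b[both_res])] > 0
  tibble::tibble(
    identity = 100 * sum(ident) / n,
    similarity = 100 * sum(ident | pos_score) / n,
    columns = n
  )
}

getAAMatrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Discriminative-conservation scan
#'
#' Finds alignment columns where every "frequent" row carries one and the
#' same residue (no gaps) that no "rare" row carries at that column --
#' the signature of residues conserved in, and unique to, frequently
#' interacting members of a group.
#'
#' @param block Aligned block tibble (columns `id`, `aligned`).
#' @param frequent_ids,rare_ids Disjoint, non-empty id sets, both present
#'   in the block.
#' @return Tibble `column` (alignment column), `residue`, `position`
#'   (ungapped position in the first frequent row).
#' @export
discriminative_conservation <- function(block, frequent_ids, rare_ids) {
  block <- validate_alignment(block)
  if (length(frequent_ids) == 0L || length(rare_ids) == 0L) {
    stop("Both id sets must be non-empty.", call. = FALSE)
  }
  if (length(intersect(frequent_ids, rare_ids)) > 0L) {
    stop("'frequent_ids' and 'rare_ids' must be disjoint.", call. = FALSE)
  }
  missing_ids <- setdiff(c(frequent_ids, rare_ids), block$id)
  if (length(missing_ids) > 0L) {
    stop("Ids not in alignment: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  rows <- function(ids) {
    do.call(rbind, strsplit(block$aligned[match(ids, block$id)], ""))
  }
  fr <- rows(frequent_ids)
  ra <- rows(rare_ids)
  first_row <- fr[1, ]
  ungapped <- cumsum(first_row != "-")
  hits <- purrr::map(seq_len(ncol(fr)), function(j) {
    col_f <- fr[, j]
    if (any(col_f == "-")) return(NULL)
    if (length(unique(col_f)) != 1L) return(NULL)
    x <- col_f[1]
    if (any(ra[, j] == x)) return(NULL)
    tibble::tibble(column = j, residue = x,
                   position = as.integer(ungapped[j]))
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L) {
    tibble::tibble(column = integer(), residue = character(),
                   position = integer())
  } else out
}
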