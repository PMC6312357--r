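#' Encode a structure-word profile
#'
#' Encodes an annotated sequence as per-residue structural symbols:
#' hydropathy class (`H`ydrophobic / `P`olar by the sign of the
#' Kyte-Doolittle value), heptad register letter (`a`-`g`, `.` outside
#' helices) and helix class (`H` inside a predicted helix block, `C`
#' coil otherwise). Structure words are the contiguous k-tuples of these
#' symbols; they drive the weighted distance used for clustering.
#'
#' @param annotation An `ecc_annotation`.
#' @param k Word length (default 3).
#' @return A `structword_profile`: list with `symbols` (tibble
#'   `position`, `hydro`, `heptad`, `helix`), `words` (character vector
#'   of the n - k + 1 words) and `k`.
#' @export
encode_structwords <- function(annotation, k = 3L) {
  stopifnot(inherits(annotation, "ecc_annotation"))
  chars <- strsplit(annotation$residues, "")[[1]]
  n <- length(chars)
  hydro <- ifelse(KD_SCALE[chars] > 0, "H", "P")
  heptad <- strsplit(annotation$register, "")[[1]]
  helix <- rep("C", n)
  for (i in seq_len(nrow(annotation$helices))) {
    helix[annotation$helices$start[i]:annotation$helices$end[i]] <- "H"
  }
  symbols <- tibble::tibble(position = seq_len(n), hydro = unname(hydro),
                            heptad = heptad, helix = helix)
  tuple <- paste0(hydro, heptad, helix)
  words <- if (n >= k) {
    vapply(seq_len(n - k + 1L), function(i) {
      paste(tuple[i:(i + k - 1L)], collapse = "")
    }, "")
  } else character()
  structure(list(id = annotation$id, symbols = symbols, words = words,
                 k = as.integer(k)),
            class = "structword_profile")
}

#' Weighted-Jaccard structure-word distance
#'
#' One minus the weighted Jaccard similarity of the two word multisets:
#' `sum(w * pmin(c1, c2)) / sum(w * pmax(c1, c2))`, where a word
#' containing an `a` or `d` heptad symbol (the coiled-coil binding
#' interface) carries weight `w_ad` and all others weight 1. Zero iff the
#' multisets are identical; two empty profiles are at distance 1.
#'
#' @param p1,p2 `structword_profile`s with the same `k`.
#' @param w_ad Weight for interface words (default 2).
#' @return Distance in `[0, 1]`.
#' @export
structword_distance <- function(p1, p2, w_ad = 2) {
  if (p1$k != p2$k) stop("Profiles have different word lengths.",
                         call. = FALSE)
  c1 <- table(p1$words)
  c2 <- table(p2$words)
  words <- union(names(c1), names(c2))
  if (length(words) == 0L) return(1)
  n1 <- as.numeric(c1[words]); n1[is.na(n1)] <- 0
  n2 <- as.numeric(c2[words]); n2[is.na(n2)] <- 0
  w <- ifelse(word_has_interface(words, p1$k), w_ad, 1)
  1 - sum(w * pmin(n1, n2)) / sum(w * pmax(n1, n2))
}

# A word is an interface word when any of its k heptad symbols is a or d.
word_has_interface <- function(words, k) {
  # symbols are fixed-width triples (hydro, heptad, helix)
  vapply(words, function(wd) {
    heptads <- substring(wd, seq(2, 3 * k, by = 3), seq(2, 3 * k, by = 3))
    any(heptads %in% c("a", "d"))
  }, logical(1), USE.NAMES = FALSE)
}

#' Structure-word distance matrix for an annotated panel
#'
#' @param annotated Output of [annotate_panel()].
#' @param k Word length (default 3).
#' @param w_ad Interface-word weight (default 2).
#' @return A symmetric matrix with zero diagonal, ids as dimnames.
#' @export
structword_distmat <- function(annotated, k = 3L, w_ad = 2) {
  profiles <- purrr::map(annotated$annotation, encode_structwords, k = k)
  n <- length(profiles)
  d <- matrix(0, n, n,
              dimnames = list(annotated$id, annotated$id))
  if (n < 2L) return(d)
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- structword_distance(profiles[[i]],
                                                profiles[[j]], w_ad = w_ad)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei agglomeration (via `ape::nj`). Negative branch
#' length estimates are clamped to zero and flagged in the
#' `clamped_branches` attribute.
#'
#' @param d Symmetric distance matrix (zero diagonal) or `dist`.
#' @return An `ape::phylo` tree; leaves are the matrix ids.
#' @export
build_nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("Neighbor joining needs at least 3 taxa.",
                         call. = FALSE)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("Distance matrix must be symmetric.", call. = FALSE)
  }
  if (any(d < -1e-12) || any(abs(diag(d)) > 1e-12)) {
    stop("Distances must be non-negative with a zero diagonal.",
         call. = FALSE)
  }
  tree <- ape::nj(stats::as.dist(d))
  clamped <- sum(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped_branches") <- clamped
  tree
}

#' Robinson-Foulds distance between two trees
#'
#' Number of bipartitions present in exactly one of the two unrooted
#' trees (the symmetric difference).
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("Trees have different leaf sets.", call. = FALSE)
  }
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}
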