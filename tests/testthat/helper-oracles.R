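# Independent oracles used against the implementation. These stay
# deliberately naive: direct enumeration / textbook formulas only.

# Weighted Jaccard over word multisets, by direct multiset enumeration.
oracle_weighted_jaccard_distance <- function(words1, words2, k, w_ad = 2) {
  all_words <- union(words1, words2)
  if (length(all_words) == 0L) return(1)
  num <- 0
  den <- 0
  for (w in all_words) {
    heptads <- substring(w, seq(2, 3 * k, by = 3), seq(2, 3 * k, by = 3))
    wt <- if (any(heptads %in% c("a", "d"))) w_ad else 1
    c1 <- sum(words1 == w)
    c2 <- sum(words2 == w)
    num <- num + wt * min(c1, c2)
    den <- den + wt * max(c1, c2)
  }
  1 - num / den
}

# Non-trivial bipartitions of an unrooted phylo tree as canonical strings.
oracle_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  n <- length(tips)
  internal <- tree$edge[tree$edge[, 2] > n, 2]
  parts <- character(0)
  for (node in internal) {
    below <- ape::extract.clade(tree, node)$tip.label
    side <- sort(below)
    other <- sort(setdiff(tips, side))
    if (length(side) < 2L || length(other) < 2L) next
    canon <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
      paste(side, collapse = ",") else paste(other, collapse = ",")
    parts <- c(parts, canon)
  }
  unique(parts)
}

oracle_rf <- function(t1, t2) {
  b1 <- oracle_bipartitions(t1)
  b2 <- oracle_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration of all
# tables with the observed margins.
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(x_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Column-by-column discriminative scan (brute force).
oracle_discriminative <- function(block, frequent_ids, rare_ids) {
  fr <- do.call(rbind,
                strsplit(block$aligned[match(frequent_ids, block$id)], ""))
  ra <- do.call(rbind,
                strsplit(block$aligned[match(rare_ids, block$id)], ""))
  hits <- integer(0)
  res <- character(0)
  for (j in seq_len(ncol(fr))) {
    col <- fr[, j]
    if (all(col != "-") && length(unique(col)) == 1L &&
        !any(ra[, j] == col[1])) {
      hits <- c(hits, j)
      res <- c(res, col[1])
    }
  }
  list(column = hits, residue = res)
}

# Random valid sequence panel for round-trip properties.
random_panel <- function(n, min_len = 10L, max_len = 150L) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  tibble::tibble(
    id = paste0("seq", seq_len(n)),
    residues = vapply(seq_len(n), function(i) {
      paste(sample(aa, sample(min_len:max_len, 1), replace = TRUE),
            collapse = "")
    }, ""),
    description = ifelse(seq_len(n) %% 2 == 0,
                         paste("demo record", seq_len(n)), "")
  )
}

make_block <- function(ids, rows) tibble::tibble(id = ids, aligned = rows)
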