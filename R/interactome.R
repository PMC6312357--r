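#' Read a Y2H mating table
#'
#' TSV with columns `bait`, `prey`, `replicate` (1-4), `growth`
#' (TRUE/FALSE: growth on media lacking His and adenine).
#'
#' @param path Path to the TSV.
#' @return Validated mating tibble.
#' @export
read_matings <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           bait = readr::col_character(),
                           prey = readr::col_character(),
                           replicate = readr::col_integer(),
                           growth = readr::col_logical()))
  validate_matings(tab)
}

validate_matings <- function(matings) {
  matings <- tibble::as_tibble(matings)
  need <- c("bait", "prey", "replicate", "growth")
  if (!all(need %in% names(matings))) {
    stop("Mating table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(!matings$replicate %in% 1:4)) {
    stop("Replicates must be 1-4 (four matings per orientation).",
         call. = FALSE)
  }
  key <- paste(matings$bait, matings$prey, matings$replicate)
  if (anyDuplicated(key)) {
    stop("Duplicate (bait, prey, replicate) row(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 3),
               collapse = "; "), call. = FALSE)
  }
  matings
}

#' Call interactions from replicated matings
#'
#' An unordered pair is retained as an edge iff the total number of
#' positive replicates across both bait/prey orientations reaches
#' `min_support` (max 8 for heteromeric pairs, 4 for self matings).
#'
#' @param matings Mating tibble (`bait`, `prey`, `replicate`, `growth`).
#' @param min_support Positive replicates required (default 3).
#' @return Edge tibble `a`, `b` (sorted within pair; `a == b` for
#'   homomeric edges), `support`.
#' @export
call_interactions <- function(matings,
                              min_support = ecc_defaults()$min_support) {
  matings <- validate_matings(matings)
  matings$a <- pmin(matings$bait, matings$prey)
  matings$b <- pmax(matings$bait, matings$prey)
  edges <- matings |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(support = sum(.data$growth), .groups = "drop") |>
    dplyr::filter(.data$support >= min_support) |>
    dplyr::arrange(.data$a, .data$b)
  edges
}

#' Build an ECC interaction network
#'
#' @param edges Edge tibble from [call_interactions()].
#' @param nodes All screened clone ids (isolated nodes matter for the
#'   summaries); defaults to the ids present in `edges`.
#' @return An `ecc_network` (list of `nodes` and `edges`).
#' @export
ecc_network <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  if (is.null(nodes)) nodes <- sort(unique(c(edges$a, edges$b)))
  stray <- setdiff(unique(c(edges$a, edges$b)), nodes)
  if (length(stray) > 0L) {
    stop("Edges reference unknown node(s): ",
         paste(stray, collapse = ", "), call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "ecc_network")
}

#' @export
print.ecc_network <- function(x, ...) {
  s <- glance(x)
  cat("<ecc_network> ", s$n_nodes, " clones, ", s$n_hetero,
      " heteromeric + ", s$n_self, " homomeric interactions\n", sep = "")
  invisible(x)
}

#' Per-node interaction counts
#'
#' Degree counts heteromeric partners plus 1 for a self-association
#' (the correlation with phenotype includes self-association).
#'
#' @param net An `ecc_network`.
#' @return Tibble `id`, `n_partners` (heteromeric), `self`, `degree`.
#' @export
network_degrees <- function(net) {
  e <- net$edges
  het <- e[e$a != e$b, ]
  partners <- table(factor(c(het$a, het$b), levels = net$nodes))
  selfs <- e$a[e$a == e$b]
  tibble::tibble(
    id = net$nodes,
    n_partners = as.integer(partners),
    self = net$nodes %in% selfs,
    degree = as.integer(partners) + as.integer(net$nodes %in% selfs)
  )
}

#' Network summary counts
#'
#' @param net An `ecc_network`.
#' @param ... Unused.
#' @return One-row tibble: `n_nodes`, `n_self` (homomeric edges),
#'   `n_hetero` (heteromeric edges), `n_nodes_with_hetero`.
#' @export
glance.ecc_network <- function(net, ...) {
  e <- net$edges
  het <- e[e$a != e$b, ]
  tibble::tibble(
    n_nodes = length(net$nodes),
    n_self = sum(e$a == e$b),
    n_hetero = nrow(het),
    n_nodes_with_hetero = length(unique(c(het$a, het$b)))
  )
}

#' @rdname glance.ecc_network
#' @export
network_summary <- function(net) glance(net)

#' Correlation between interaction count and phenotype strength
#'
#' Pearson correlation (with the two-sided t-transform p value) between
#' each clone's interaction count (heteromeric partners, + 1 for
#' self-association) and its ordinal response category in one species.
#'
#' @param net An `ecc_network`.
#' @param phenotypes Phenotype tibble (`ecc_id`, `species`, `category`).
#' @param species Species to correlate against (default `"At"`).
#' @return One-row tibble `r`, `p`, `n`.
#' @export
degree_phenotype_correlation <- function(net, phenotypes, species = "At") {
  phenotypes <- validate_phenotypes(phenotypes)
  ph <- phenotypes[phenotypes$species == species, ]
  deg <- network_degrees(net)
  missing_ph <- setdiff(deg$id, ph$ecc_id)
  if (length(missing_ph) > 0L) {
    stop("No ", species, " phenotype for node(s): ",
         paste(utils::head(missing_ph, 5), collapse = ", "), call. = FALSE)
  }
  x <- deg$degree
  y <- ph$category[match(deg$id, ph$ecc_id)]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("Undefined correlation: zero variance in ",
         if (stats::var(x) == 0) "interaction counts" else "phenotype",
         ".", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Fisher test for differential interaction frequency between group pairs
#'
#' Classifies every heteromeric dyad (unordered node pair) by whether its
#' two group labels match the focal pair of group sets or the reference
#' pair, builds the 2x2 table edge-present x dyad-class, and applies the
#' two-sided Fisher exact test. The odds ratio reported is the sample
#' (cross-product) ratio so equal densities give exactly 1.
#'
#' @param net An `ecc_network`.
#' @param groups Named character vector (or tibble `id`, `group`) giving
#'   each node's group.
#' @param focal,reference Each a list of two character vectors of group
#'   labels (the two sides of the dyad class).
#' @return One-row tibble `odds_ratio`, `p`, plus the table cells.
#' @export
group_pair_interaction_test <- function(net, groups,
                                        focal, reference) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(groups$group, groups$id)
  }
  missing_g <- setdiff(net$nodes, names(groups))
  if (length(missing_g) > 0L) {
    stop("No group for node(s): ",
         paste(utils::head(missing_g, 5), collapse = ", "), call. = FALSE)
  }
  nodes <- net$nodes
  dyads <- which(upper.tri(matrix(0, length(nodes), length(nodes))),
                 arr.ind = TRUE)
  ga <- groups[nodes[dyads[, 1]]]
  gb <- groups[nodes[dyads[, 2]]]
  in_pair <- function(pair) {
    (ga %in% pair[[1]] & gb %in% pair[[2]]) |
      (ga %in% pair[[2]] & gb %in% pair[[1]])
  }
  cls <- dplyr::case_when(in_pair(focal) ~ "focal",
                          in_pair(reference) ~ "reference",
                          TRUE ~ NA_character_)
  het <- net$edges[net$edges$a != net$edges$b, ]
  key <- paste(pmin(nodes[dyads[, 1]], nodes[dyads[, 2]]),
               pmax(nodes[dyads[, 1]], nodes[dyads[, 2]]))
  has_edge <- key %in% paste(het$a, het$b)
  keep <- !is.na(cls)
  if (!any(cls[keep] == "focal") || !any(cls[keep] == "reference")) {
    stop("Degenerate table: a dyad class is empty.", call. = FALSE)
  }
  tab <- table(edge = factor(has_edge[keep], levels = c(TRUE, FALSE)),
               class = factor(cls[keep], levels = c("focal", "reference")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  or <- (a * d) / (b * c)  # sample odds ratio; may be Inf/NaN at the edges
  tibble::tibble(odds_ratio = or, p = ft$p.value,
                 focal_edges = as.integer(a),
                 focal_dyads = as.integer(a + c),
                 reference_edges = as.integer(b),
                 reference_dyads = as.integer(b + d))
}

#' Clones with a higher-affinity heteromeric partner
#'
#' Affinity is operationalized as replicate support; a clone qualifies
#' when its best heteromeric edge support strictly exceeds its
#' self-edge support (0 when it has no self edge).
#'
#' @param net An `ecc_network`.
#' @return Character vector of clone ids.
#' @export
higher_affinity_partners <- function(net) {
  e <- net$edges
  het <- e[e$a != e$b, ]
  self_support <- stats::setNames(rep(0L, length(net$nodes)), net$nodes)
  selfs <- e[e$a == e$b, ]
  self_support[selfs$a] <- selfs$support
  best_het <- stats::setNames(rep(0L, length(net$nodes)), net$nodes)
  for (i in seq_len(nrow(het))) {
    best_het[het$a[i]] <- max(best_het[het$a[i]], het$support[i])
    best_het[het$b[i]] <- max(best_het[het$b[i]], het$support[i])
  }
  sort(names(best_het)[best_het > self_support & best_het > 0])
}

#' Cross-species persistence of ECC activity
#'
#' Counts, per clone, the species in which its response category reaches
#' `theta_resp` (necrosis or stronger), and aggregates activity per
#' species and species combination.
#'
#' @param phenotypes Phenotype tibble (`ecc_id`, `species`, `category`).
#' @param theta_resp Named per-species activity threshold (default
#'   category >= 2 in each species).
#' @return List with `per_ecc` (tibble `ecc_id`, `persistence`,
#'   `active_in`) and `per_species` (tibble `species`, `n_active`,
#'   `n_scored`).
#' @export
cross_species_persistence <- function(phenotypes,
                                      theta_resp = c(At = 2, Nb = 2, Ls = 2)) {
  phenotypes <- validate_phenotypes(phenotypes)
  phenotypes$active <-
    phenotypes$category >= theta_resp[phenotypes$species]
  per_ecc <- phenotypes |>
    dplyr::group_by(.data$ecc_id) |>
    dplyr::summarise(
      persistence = sum(.data$active),
      active_in = paste(sort(.data$species[.data$active]), collapse = "+"),
      .groups = "drop")
  per_species <- phenotypes |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(n_active = sum(.data$active),
                     n_scored = dplyr::n(), .groups = "drop")
  list(per_ecc = per_ecc, per_species = per_species)
}

#' Export a network as GraphML (Cytoscape-compatible) and edge TSV
#'
#' @param net An `ecc_network`.
#' @param path Output path (`.graphml` or `.tsv` decides the format).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  if (grepl("\\.tsv$", path)) {
    readr::write_tsv(net$edges, path)
  } else {
    g <- igraph::graph_from_data_frame(
      net$edges[, c("a", "b", "support")],
      directed = FALSE,
      vertices = data.frame(name = net$nodes))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Plot an interaction network
#'
#' @param object An `ecc_network`.
#' @param groups Optional named group vector for node colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecc_network <- function(object, groups = NULL, ...) {
  g <- igraph::graph_from_data_frame(
    object$edges[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = object$nodes))
  xy <- with_seed(1L, igraph::layout_with_fr(g))  # layout only
  nodes <- tibble::tibble(id = object$nodes, x = xy[, 1], y = xy[, 2])
  if (!is.null(groups)) nodes$group <- groups[nodes$id]
  e <- object$edges
  seg <- tibble::tibble(
    x = nodes$x[match(e$a, nodes$id)], y = nodes$y[match(e$a, nodes$id)],
    xend = nodes$x[match(e$b, nodes$id)],
    yend = nodes$y[match(e$b, nodes$id)])
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          colour = "grey60") +
    ggplot2::theme_void()
  if (is.null(groups)) {
    p + ggplot2::geom_point(data = nodes,
                            ggplot2::aes(x = .data$x, y = .data$y), size = 3)
  } else {
    p + ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$group),
      size = 3)
  }
}
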