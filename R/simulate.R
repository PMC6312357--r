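#' Synthetic-data generators
#'
#' Every input the pipeline consumes can be generated with the
#' statistical structure the analysis assumes: group-structured ECC
#' panels with planted features and ground truth, replicated Y2H screens
#' with group-dependent edge probabilities, and single-QTL F2
#' populations. All generators are deterministic given their seed and
#' leave the global RNG state untouched.
#'
#' @name ecc_simulate
NULL

# Run code under a local, seeded RNG; restores the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Residue vocabularies of the generator. Helix fillers exclude G (so the
# only V/I G dipeptide in a noise-free sequence is the planted pre-P-loop
# VG) and exclude R/D/V/I (R would let a 7-window of fillers dip below the
# helix threshold; D only ever occurs in the charged motif and EDVID, so
# EDVID cannot arise by accident).
GEN_HELIX_FILLER <- c("A", "E", "K", "Q", "M")
GEN_TURN_SET     <- c("P", "N", "S", "G")
GEN_CCVX_SET     <- c("S", "N", "T", "G", "P")
GEN_POLAR_SET    <- c("E", "K", "Q")
# Fixed charged-motif multiset: 5 acidic, 4 basic; its top-6 propensity
# sum plus a P/G flank stays below a 6-residue run over the helix
# threshold, so the charged island is never predicted as a helix block.
GEN_CHARGED_MULTISET <- c("E", "D", "D", "D", "D", "K", "K", "R", "R")
GEN_WALKER_A <- "GMGGLGKTT"

#' Specify a synthetic ECC panel
#'
#' Defaults reproduce the study conditions: 56 receptor N-termini split
#' into the published group sizes (6 A, 8 C, 14 D, with the remainder in
#' B and the CC-less E outgroup).
#'
#' @param n_a,n_b,n_c,n_d,n_e Sequences per group.
#' @param helix_len Range (min, max) for the plain heptad helices.
#' @param ccvx_len Candidate CCVX linker lengths (canonical 16-18).
#' @param epsilon Substitution noise rate in `[0, 1]` applied outside
#'   protected anchors.
#' @param protect_anchors Keep planted motif anchors (and the initiator
#'   Met) noise-free (default TRUE).
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(n_a = 6L, n_b = 20L, n_c = 8L, n_d = 14L, n_e = 8L,
                       helix_len = c(14L, 21L), ccvx_len = 16:18,
                       epsilon = 0, protect_anchors = TRUE) {
  counts <- c(A = n_a, B = n_b, C = n_c, D = n_d, E = n_e)
  if (any(counts < 0L)) stop("Group counts must be >= 0.", call. = FALSE)
  if (epsilon < 0 || epsilon > 1) {
    stop("'epsilon' must be in [0, 1].", call. = FALSE)
  }
  if (any(ccvx_len < 1L)) stop("CCVX lengths must be positive.", call. = FALSE)
  structure(list(counts = counts, helix_len = helix_len,
                 ccvx_len = as.integer(ccvx_len), epsilon = epsilon,
                 protect_anchors = protect_anchors),
            class = "panel_spec")
}

#' Generate a synthetic ECC panel with ground truth
#'
#' Each sequence is assembled from a group-specific N-terminal cap,
#' helix blocks with L/I/V planted at heptad a/d positions, P/G-rich
#' turns, a CCVX linker of planted length, the charged motif at
#' -11..-3 of a planted VG pre-P-loop, and a Walker-A P-loop terminus.
#' Group A starts with the synthetic CC_R signature ([rpw8_signature()]),
#' Group B with the acylation-competent `MGGCS` cap, Group D carries the
#' 10-polar stretch before EDVID, Group C a deliberately low-polar
#' stretch, and Group E has no helix at all. Substitution noise at rate
#' `epsilon` is applied outside protected anchors.
#'
#' @param spec A [panel_spec()].
#' @param seed Integer seed (required: generators are always explicit
#'   about their randomness).
#' @return List with `panel` (tibble `id`, `residues`, `description`) and
#'   `truth` (tibble of planted coordinates and group labels, plus a
#'   `helices` list-column).
#' @export
#' @examples
#' p <- gen_ecc_panel(panel_spec(n_d = 2), seed = 7)
#' p$truth$group
gen_ecc_panel <- function(spec = panel_spec(), seed) {
  if (missing(seed)) stop("'seed' is required.", call. = FALSE)
  with_seed(seed, {
    groups <- rep(names(spec$counts), times = spec$counts)
    rows <- purrr::imap(groups, function(g, i) {
      gen_one_ecc(sprintf("ECC%03d_%s", i, g), g, spec)
    })
    panel <- dplyr::bind_rows(purrr::map(rows, "panel"))
    truth <- dplyr::bind_rows(purrr::map(rows, "truth"))
    truth$helices <- purrr::map(rows, "helices")
    list(panel = panel, truth = truth)
  })
}

heptad_block <- function(len) {
  pos <- seq_len(len) - 1L
  ad <- (pos %% 7L) %in% c(0L, 3L)
  chars <- character(len)
  chars[ad] <- sample(HEPTAD_HYDROPHOBIC, sum(ad), replace = TRUE)
  chars[!ad] <- sample(GEN_HELIX_FILLER, sum(!ad), replace = TRUE)
  paste(chars, collapse = "")
}

gen_turn <- function(len = 6L) {
  first <- sample(c("P", "N"), 1L)
  rest <- sample(GEN_TURN_SET, len - 1L, replace = TRUE)
  paste(c(first, rest), collapse = "")
}

# H2b: 14 heptad residues, a planted terminal L at offset 14 (heptad 'a'),
# then 5 filler residues. CC-END is that L -- interior to the block so the
# smoothed helix predictor always covers it.
gen_h2b <- function() {
  pad <- paste(sample(GEN_HELIX_FILLER, 5L, replace = TRUE), collapse = "")
  list(seq = heptad_block(14L) %+% "L" %+% pad, cc_end_offset = 14L)
}

# CCVX is defined from the residue after CC-END, so the 5 helix-filler
# residues padding H2b after its terminal L count toward the planted CCVX
# length; the explicit linker segment is 5 residues shorter.
gen_tail <- function(spec, pad = 5L) {
  ccvx_len <- if (length(spec$ccvx_len) == 1L) spec$ccvx_len
              else sample(spec$ccvx_len, 1L)
  linker_len <- ccvx_len - pad
  if (linker_len < 3L) stop("CCVX lengths must be >= 8.", call. = FALSE)
  ccvx <- paste(c(sample(GEN_CCVX_SET, linker_len - 2L, replace = TRUE),
                  sample(c("P", "G"), 2L, replace = TRUE)), collapse = "")
  charged <- paste(sample(GEN_CHARGED_MULTISET), collapse = "")
  x8 <- paste(sample(c("S", "T", "N"), 8L, replace = TRUE), collapse = "")
  x3 <- paste(sample(c("S", "T", "N"), 3L, replace = TRUE), collapse = "")
  preploop <- "VG" %+% x8 %+% sample(c("L", "I"), 1L) %+% x3 %+% "L"
  list(ccvx = ccvx, charged = charged, spacer = "PG",
       preploop = preploop, walker = GEN_WALKER_A,
       ccvx_len = as.integer(ccvx_len))
}

rand_len <- function(range) {
  if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1L)
}

gen_one_ecc <- function(id, group, spec) {
  segs <- list()           # named segments, in order
  helix_spans <- list()    # planted helices (label, start, end), filled below
  pos <- 0L
  push <- function(name, s) {
    segs[[length(segs) + 1L]] <<- list(name = name, seq = s, start = pos + 1L)
    pos <<- pos + nchar(s)
  }
  mark_helix <- function(label) {
    last <- segs[[length(segs)]]
    helix_spans[[length(helix_spans) + 1L]] <<-
      tibble::tibble(label = label,
                     start = last$start,
                     end = last$start + nchar(last$seq) - 1L)
  }

  hl <- function() rand_len(spec$helix_len)

  if (group == "A") {
    push("cap", "M")
    push("helix", rpw8_signature()); mark_helix("H1")
    push("turn", gen_turn())
    push("helix", heptad_block(hl())); mark_helix("H2a")
    push("turn", gen_turn())
    h2b <- gen_h2b()
    push("helix", h2b$seq); mark_helix("H2b")
  } else if (group %in% c("B", "C", "D")) {
    push("cap", if (group == "B") "MGGCS" else "MAEK")
    push("helix", heptad_block(hl())); mark_helix("H1a")
    push("turn", gen_turn())
    push("helix", heptad_block(hl())); mark_helix("H1b")
    push("turn", gen_turn())
    if (group == "B") {
      push("helix", heptad_block(hl())); mark_helix("H2a")
    } else {
      stretch <- if (group == "D") {
        paste(sample(GEN_POLAR_SET, 10L, replace = TRUE), collapse = "")
      } else {
        # low-polar: at most 4 of 10 polar so Group C never trips the
        # Group D rule
        n_polar <- sample(0:4, 1L)
        chars <- c(sample(c("E", "K"), n_polar, replace = TRUE),
                   sample(c("A", "M"), 10L - n_polar, replace = TRUE))
        paste(sample(chars), collapse = "")
      }
      h2a <- heptad_block(21L) %+% stretch %+% "EDVID"
      push("helix", h2a); mark_helix("H2a")
    }
    push("turn", gen_turn())
    h2b <- gen_h2b()
    push("helix", h2b$seq); mark_helix("H2b")
  } else {  # Group E: no clearly defined CC domain
    push("cap", "MAEK")
    coil <- paste(sample(GEN_CCVX_SET, 50L + sample(0:20, 1L),
                         replace = TRUE), collapse = "")
    push("coil", coil)
    h2b <- NULL
  }

  tail <- gen_tail(spec)
  push("ccvx", tail$ccvx)
  push("charged", tail$charged)
  push("spacer", tail$spacer)
  push("preploop", tail$preploop)
  push("walker", tail$walker)

  seqs <- vapply(segs, `[[`, "", "seq")
  starts <- vapply(segs, `[[`, 0L, "start")
  names(starts) <- vapply(segs, `[[`, "", "name")
  residues <- paste(seqs, collapse = "")

  # Planted coordinates
  seg_start <- function(name) unname(starts[names(starts) == name][1])
  vg <- seg_start("preploop")
  charged_start <- seg_start("charged")
  ploop_start <- seg_start("walker")
  helices <- if (length(helix_spans)) dplyr::bind_rows(helix_spans)
             else tibble::tibble(label = character(), start = integer(),
                                 end = integer())
  cc_end <- if (group == "E") NA_integer_ else {
    h2b_row <- helices[helices$label == "H2b", ]
    h2b_row$start + 14L
  }
  edvid_start <- if (group %in% c("C", "D")) {
    h2a_row <- helices[helices$label == "H2a", ]
    h2a_row$end - 4L
  } else NA_integer_
  polar_start <- if (group == "D") edvid_start - 10L else NA_integer_
  charged_chars <- strsplit(tail$charged, "")[[1]]

  truth <- tibble::tibble(
    id = id, group = group,
    length = nchar(residues),
    edvid_start = edvid_start,
    polar_start = polar_start,
    vg = vg,
    ploop_start = ploop_start,
    charged_start = charged_start,
    charged_end = charged_start + 8L,
    n_acidic = sum(charged_chars %in% ACIDIC_RESIDUES),
    n_basic = sum(charged_chars %in% BASIC_RESIDUES),
    cc_end = cc_end,
    ccvx_start = if (group == "E") NA_integer_ else cc_end + 1L,
    ccvx_length = if (group == "E") NA_integer_
                  else as.integer(charged_start - 1L - cc_end),
    ecc_boundary = ploop_start - 1L,
    myristoylation = group == "B",
    palmitoylation = group == "B"
  )

  if (spec$epsilon > 0) {
    residues <- add_noise(residues, spec, truth, group)
  }

  list(
    panel = tibble::tibble(id = id, residues = residues,
                           description = paste("synthetic group", group)),
    truth = truth,
    helices = helices
  )
}

add_noise <- function(residues, spec, truth, group) {
  chars <- strsplit(residues, "")[[1]]
  protected <- logical(length(chars))
  if (spec$protect_anchors) {
    protect <- function(s, e) {
      if (!is.na(s)) protected[s:e] <<- TRUE
    }
    protect(1L, min(5L, length(chars)))          # initiator Met + cap
    protect(truth$edvid_start, truth$edvid_start + 4L)
    protect(truth$polar_start, truth$polar_start + 9L)
    protect(truth$vg, truth$vg + 14L)
    protect(truth$ploop_start, truth$ploop_start + 8L)
    protect(truth$charged_start - 2L, truth$charged_end + 2L)
    protect(truth$cc_end, truth$cc_end)
  } else {
    protected[1] <- TRUE  # noise never mutates the initiator Met
  }
  hit <- runif(length(chars)) < spec$epsilon & !protected
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(old) {
      sample(setdiff(AA_ALPHABET, old), 1L)
    }, "")
  }
  paste(chars, collapse = "")
}

#' Specify a synthetic Y2H screen
#'
#' Interaction propensities emulate the observed interactome: edges occur
#' at similar frequencies between sequence-related and unrelated ECCs
#' (~8% of heteromeric dyads), homomeric association is rare (~9% of
#' clones), and each of the 4 matings per orientation can drop out or
#' fire spuriously.
#'
#' @param edge_p Either a single probability applied to every group pair
#'   or a symmetric 5x5 matrix (rows/cols A-E) of dyad probabilities.
#' @param self_p Self-association probability (scalar or length-5 named
#'   vector A-E).
#' @param fn,fp Per-replicate false-negative / false-positive rates.
#' @return A `y2h_model` list.
#' @export
y2h_model <- function(edge_p = 0.08, self_p = 0.09, fn = 0.1, fp = 0.01) {
  gs <- c("A", "B", "C", "D", "E")
  if (length(edge_p) == 1L) {
    edge_p <- matrix(edge_p, 5, 5, dimnames = list(gs, gs))
  }
  if (!isTRUE(all.equal(edge_p, t(edge_p)))) {
    stop("'edge_p' must be symmetric.", call. = FALSE)
  }
  if (length(self_p) == 1L) self_p <- stats::setNames(rep(self_p, 5), gs)
  probs <- c(edge_p, self_p, fn, fp)
  if (any(probs < 0 | probs > 1)) {
    stop("All probabilities must be in [0, 1].", call. = FALSE)
  }
  structure(list(edge_p = edge_p, self_p = self_p, fn = fn, fp = fp),
            class = "y2h_model")
}

#' Generate a replicated Y2H mating screen
#'
#' Latent true edges are drawn per dyad from the group-pair probability;
#' each orientation (bait/prey and prey/bait; a single orientation for
#' self matings) is then scored in 4 replicates, positive with
#' probability `1 - fn` for a true edge and `fp` otherwise.
#'
#' @param ids Character vector of clone ids.
#' @param groups Group label (A-E) per id.
#' @param model A [y2h_model()].
#' @param seed Integer seed.
#' @return List with `matings` (tibble `bait`, `prey`, `replicate`,
#'   `growth`) and `truth` (tibble `a`, `b`, `true_edge`).
#' @export
gen_y2h_screen <- function(ids, groups, model = y2h_model(), seed) {
  if (missing(seed)) stop("'seed' is required.", call. = FALSE)
  stopifnot(length(ids) == length(groups))
  with_seed(seed, {
    n <- length(ids)
    pairs <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
    a <- pairs[, "row"]; b <- pairs[, "col"]
    p <- ifelse(a == b,
                model$self_p[groups[a]],
                model$edge_p[cbind(groups[a], groups[b])])
    true_edge <- stats::runif(length(p)) < p
    truth <- tibble::tibble(a = ids[a], b = ids[b], true_edge = true_edge)
    mat_rows <- purrr::pmap(list(ids[a], ids[b], true_edge),
                            function(ia, ib, te) {
      orientations <- if (ia == ib) list(c(ia, ib))
                      else list(c(ia, ib), c(ib, ia))
      dplyr::bind_rows(purrr::map(orientations, function(o) {
        p_pos <- if (te) 1 - model$fn else model$fp
        tibble::tibble(bait = o[1], prey = o[2], replicate = 1:4,
                       growth = stats::runif(4) < p_pos)
      }))
    })
    matings <- dplyr::bind_rows(mat_rows)
    list(matings = matings, truth = truth)
  })
}

#' Specify a single-QTL F2 design
#'
#' Defaults reproduce the mapping design: 75 F2 individuals scored on an
#' ordinal 1-5 scale, a genome of 5 chromosomes with 10 markers spaced
#' 10 cM apart, and a single incompletely dominant locus (d = a/2) whose
#' additive effect explains ~30% of the phenotypic variance against a
#' unit-variance residual.
#'
#' @param n Individuals.
#' @param n_chr,markers_per_chr,spacing Map layout (positions start at 0).
#' @param qtl_chr,qtl_pos QTL location in cM.
#' @param a Additive effect (default sqrt(16*0.3/(9*0.7)), i.e. 30%
#'   variance explained with d = a/2 and residual sd 1).
#' @param d Dominance deviation (default `a / 2`).
#' @param sigma Residual standard deviation.
#' @param missing Per-genotype missing rate.
#' @return A `qtl_model` list.
#' @export
qtl_model <- function(n = 75L, n_chr = 5L, markers_per_chr = 10L,
                      spacing = 10, qtl_chr = 3L, qtl_pos = 40,
                      a = sqrt(16 * 0.3 / (9 * 0.7)), d = a / 2,
                      sigma = 1, missing = 0) {
  if (n < 10L) stop("'n' must be >= 10.", call. = FALSE)
  chr_len <- (markers_per_chr - 1L) * spacing
  if (qtl_chr > n_chr || qtl_pos < 0 || qtl_pos > chr_len) {
    stop("QTL position must lie on the map.", call. = FALSE)
  }
  structure(list(n = as.integer(n), n_chr = as.integer(n_chr),
                 markers_per_chr = as.integer(markers_per_chr),
                 spacing = spacing, qtl_chr = as.integer(qtl_chr),
                 qtl_pos = qtl_pos, a = a, d = d, sigma = sigma,
                 missing = missing),
            class = "qtl_model")
}

haldane_r <- function(cm) (1 - exp(-2 * cm / 100)) / 2

# One gamete per chromosome: Markov chain of parental alleles along the
# marker positions with Haldane recombination fractions.
sim_gamete <- function(positions, n) {
  m <- length(positions)
  alleles <- matrix(0L, n, m)
  alleles[, 1] <- stats::rbinom(n, 1L, 0.5)
  if (m > 1L) {
    for (j in 2:m) {
      r <- haldane_r(positions[j] - positions[j - 1])
      flip <- stats::rbinom(n, 1L, r)
      alleles[, j] <- (alleles[, j - 1] + flip) %% 2L
    }
  }
  alleles
}

#' Generate an F2 population with a single planted QTL
#'
#' Genotypes arise from per-chromosome Markov recombination under the
#' Haldane map function; the continuous phenotype is
#' `a * x + d * z + Normal(0, sigma)` with additive code x in {-1, 0, 1}
#' and heterozygote indicator z, discretized onto the ordinal 1-5 scale
#' at its empirical quintiles.
#'
#' @param model A [qtl_model()].
#' @param seed Integer seed.
#' @return An `f2_population`: list with `geno` (n x markers character
#'   matrix of AA/AB/BB, NA for missing), `map` (tibble `marker`, `chr`,
#'   `pos`), `phenotype` (integer 1-5) and `truth` (planted QTL location,
#'   effects and the continuous phenotype).
#' @export
#' @examples
#' pop <- gen_f2_population(qtl_model(n = 20), seed = 1)
#' table(pop$phenotype)
gen_f2_population <- function(model = qtl_model(), seed) {
  if (missing(seed)) stop("'seed' is required.", call. = FALSE)
  with_seed(seed, {
    positions <- seq(0, by = model$spacing,
                     length.out = model$markers_per_chr)
    geno_chr <- vector("list", model$n_chr)
    qtl_geno <- NULL
    for (chr in seq_len(model$n_chr)) {
      pos <- positions
      if (chr == model$qtl_chr) {
        # the QTL rides along as a pseudo-locus (possibly between markers)
        pos <- sort(unique(c(pos, model$qtl_pos)))
      }
      g <- sim_gamete(pos, model$n) + sim_gamete(pos, model$n)  # 0/1/2
      if (chr == model$qtl_chr) {
        qtl_geno <- g[, match(model$qtl_pos, pos)]
      }
      geno_chr[[chr]] <- g[, match(positions, pos), drop = FALSE]
    }
    geno_num <- do.call(cbind, geno_chr)
    x <- qtl_geno - 1L                 # additive code -1/0/+1
    z <- as.integer(qtl_geno == 1L)    # heterozygote indicator
    continuous <- model$a * x + model$d * z +
      stats::rnorm(model$n, 0, model$sigma)
    cuts <- stats::quantile(continuous, probs = c(0.2, 0.4, 0.6, 0.8))
    phenotype <- findInterval(continuous, cuts) + 1L

    geno <- matrix(c("AA", "AB", "BB")[geno_num + 1L],
                   nrow = model$n)
    if (model$missing > 0) {
      geno[stats::runif(length(geno)) < model$missing] <- NA_character_
    }
    map <- tibble::tibble(
      marker = paste0("M", rep(seq_len(model$n_chr),
                               each = model$markers_per_chr), "_",
                      rep(seq_len(model$markers_per_chr), model$n_chr)),
      chr = rep(seq_len(model$n_chr), each = model$markers_per_chr),
      pos = rep(positions, model$n_chr)
    )
    colnames(geno) <- map$marker
    structure(
      list(geno = geno, map = map, phenotype = phenotype,
           truth = list(qtl_chr = model$qtl_chr, qtl_pos = model$qtl_pos,
                        a = model$a, d = model$d,
                        continuous = continuous, qtl_geno = qtl_geno)),
      class = "f2_population")
  })
}
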