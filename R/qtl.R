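#' Assemble an F2 population from genotype, map and phenotype tables
#'
#' @param geno Matrix or data frame of genotypes (individuals x markers,
#'   codes AA/AB/BB, NA for missing).
#' @param map Tibble `marker`, `chr`, `pos` (cM, sorted within
#'   chromosome).
#' @param phenotype Numeric/ordinal phenotype per individual (the study
#'   design scores 1-5).
#' @return An `f2_population`.
#' @export
f2_population <- function(geno, map, phenotype) {
  geno <- as.matrix(geno)
  map <- tibble::as_tibble(map)
  if (!all(c("marker", "chr", "pos") %in% names(map))) {
    stop("Map needs columns marker, chr, pos.", call. = FALSE)
  }
  if (anyDuplicated(map$marker)) {
    stop("Marker names must be unique.", call. = FALSE)
  }
  if (any(map$pos < 0)) stop("Map positions must be >= 0.", call. = FALSE)
  unsorted <- map |>
    dplyr::group_by(.data$chr) |>
    dplyr::summarise(ok = !is.unsorted(.data$pos), .groups = "drop")
  if (!all(unsorted$ok)) {
    stop("Map positions must be sorted within each chromosome.",
         call. = FALSE)
  }
  if (ncol(geno) != nrow(map)) {
    stop("Genotype columns (", ncol(geno), ") != markers in map (",
         nrow(map), ").", call. = FALSE)
  }
  if (nrow(geno) != length(phenotype)) {
    stop("Individuals in genotypes (", nrow(geno),
         ") != phenotypes (", length(phenotype), ").", call. = FALSE)
  }
  bad <- !(geno %in% c("AA", "AB", "BB") | is.na(geno))
  if (any(bad)) {
    stop("Genotypes must be AA/AB/BB or NA.", call. = FALSE)
  }
  colnames(geno) <- map$marker
  structure(list(geno = geno, map = map,
                 phenotype = as.numeric(phenotype), truth = NULL),
            class = "f2_population")
}

#' Read an F2 population from CSV files
#'
#' @param geno_path CSV of individuals x markers (AA/AB/BB/NA), first
#'   column an individual id.
#' @param map_path CSV with columns marker, chr, pos.
#' @param pheno_path CSV with a `phenotype` column.
#' @return An `f2_population`.
#' @export
read_f2_population <- function(geno_path, map_path, pheno_path) {
  g <- readr::read_csv(geno_path, show_col_types = FALSE)
  geno <- as.matrix(g[, -1])
  map <- readr::read_csv(map_path, show_col_types = FALSE)
  ph <- readr::read_csv(pheno_path, show_col_types = FALSE)
  f2_population(geno, map, ph$phenotype)
}

# Numeric genotype codes per marker: additive -1/0/+1, dominance 0/1.
geno_codes <- c(AA = -1, AB = 0, BB = 1)

#' Single-marker LOD scan
#'
#' At each marker the phenotype is regressed on the additive code
#' (AA = -1, AB = 0, BB = +1) plus a heterozygote dominance indicator,
#' complete-case; `LOD = (n/2) log10(RSS_null / RSS_full)`. Markers with
#' fewer than two observed genotype classes get LOD 0 with a flag;
#' perfect fits are capped at `lod_max` with a flag.
#'
#' @param pop An `f2_population`.
#' @param lod_max Cap for degenerate perfect fits (default 50).
#' @return An `ecc_scan` tibble: `marker`, `chr`, `pos`, `lod`, `n`,
#'   `flag` (`""`, `"monomorphic"` or `"perfect_fit"`).
#' @export
marker_scan <- function(pop, lod_max = ecc_defaults()$lod_max) {
  res <- scan_lod_matrix(pop$geno, pop$phenotype, lod_max = lod_max)
  out <- tibble::tibble(
    marker = pop$map$marker, chr = pop$map$chr, pos = pop$map$pos,
    lod = unname(res$lod), n = res$n, flag = res$flag
  )
  class(out) <- c("ecc_scan", class(out))
  out
}

# Vectorized over markers: class sums via indicator masks. Used both for
# the observed scan and for the permutation null, where only the
# phenotype vector changes.
scan_masks <- function(geno) {
  list(
    obs = !is.na(geno),
    cls = lapply(c("AA", "AB", "BB"), function(g) !is.na(geno) & geno == g)
  )
}

scan_lod_masks <- function(masks, y, lod_max) {
  obs <- masks$obs
  n_m <- colSums(obs)
  y2 <- as.vector(crossprod(y^2, obs))
  s_all <- as.vector(crossprod(y, obs))
  rss0 <- y2 - s_all^2 / n_m
  rss1 <- y2
  n_classes <- rep(0L, ncol(obs))
  for (cl in masks$cls) {
    n_k <- colSums(cl)
    s_k <- as.vector(crossprod(y, cl))
    present <- n_k > 0L
    n_classes <- n_classes + present
    rss1[present] <- rss1[present] - (s_k[present]^2 / n_k[present])
  }
  lod <- (n_m / 2) * log10(pmax(rss0, 0) / pmax(rss1, .Machine$double.eps))
  flag <- rep("", ncol(obs))
  mono <- n_classes < 2L | rss0 <= .Machine$double.eps
  perfect <- !mono & rss1 <= 1e-10 * pmax(rss0, 1)
  lod[mono] <- 0
  flag[mono] <- "monomorphic"
  lod[perfect] <- lod_max
  flag[perfect] <- "perfect_fit"
  lod[lod < 0] <- 0
  list(lod = lod, n = as.integer(n_m), flag = flag)
}

scan_lod_matrix <- function(geno, y, lod_max) {
  scan_lod_masks(scan_masks(geno), y, lod_max)
}

#' Genome-wide permutation threshold for the LOD scan
#'
#' Churchill-Doerge scheme: the phenotype vector is permuted against the
#' genotype rows (preserving marker LD) `n_perm` times; the threshold is
#' the empirical `1 - alpha` quantile of the genome-wide maximum LOD.
#'
#' @param pop An `f2_population`.
#' @param n_perm Number of permutations (>= 100; the study design used
#'   1,000).
#' @param alpha Genome-wide type-I error (default 0.05).
#' @param seed Integer seed (threshold is deterministic given the seed).
#' @param lod_max Perfect-fit cap passed through to the scan.
#' @return Numeric threshold (attribute `max_lods` carries the null
#'   distribution).
#' @export
permutation_threshold <- function(pop, n_perm = ecc_defaults()$n_perm,
                                  alpha = ecc_defaults()$alpha, seed,
                                  lod_max = ecc_defaults()$lod_max) {
  if (n_perm < 100L) stop("'n_perm' must be >= 100.", call. = FALSE)
  if (missing(seed)) stop("'seed' is required.", call. = FALSE)
  masks <- scan_masks(pop$geno)
  max_lods <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      yp <- sample(pop$phenotype)
      max(scan_lod_masks(masks, yp, lod_max)$lod)
    }, numeric(1))
  })
  thr <- unname(stats::quantile(max_lods, probs = 1 - alpha))
  attr(thr, "max_lods") <- max_lods
  thr
}

#' LOD support interval around a scan peak
#'
#' Maximal contiguous cM interval on the peak's chromosome where the LOD
#' curve stays within `drop` of the peak, widened to the first flanking
#' marker below the drop on each side (chromosome ends when none).
#'
#' @param scan An `ecc_scan` from [marker_scan()].
#' @param peak_marker Marker name of the peak; defaults to the genome-wide
#'   maximum.
#' @param drop LOD drop defining the interval (default 1.5).
#' @return One-row tibble `chr`, `start`, `end`, `peak_marker`,
#'   `peak_lod`.
#' @export
lod_support_interval <- function(scan, peak_marker = NULL,
                                 drop = ecc_defaults()$drop) {
  if (is.null(peak_marker)) {
    peak_marker <- scan$marker[which.max(scan$lod)]
  }
  pk <- match(peak_marker, scan$marker)
  if (is.na(pk)) stop("Unknown peak marker.", call. = FALSE)
  chr <- scan$chr[pk]
  s <- scan[scan$chr == chr, ]
  i <- match(peak_marker, s$marker)
  ok <- s$lod >= s$lod[i] - drop
  lo <- i
  while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- i
  while (hi < nrow(s) && ok[hi + 1L]) hi <- hi + 1L
  # widen to the flanking markers just outside the plateau
  start <- s$pos[max(lo - 1L, 1L)]
  end <- s$pos[min(hi + 1L, nrow(s))]
  tibble::tibble(chr = chr, start = start, end = end,
                 peak_marker = peak_marker, peak_lod = s$lod[i])
}

#' Full QTL scan with threshold and support intervals
#'
#' @param pop An `f2_population`.
#' @param n_perm,alpha,seed,lod_max,drop See [permutation_threshold()]
#'   and [lod_support_interval()].
#' @param method `"regression"` (additive + dominance LOD) or
#'   `"kruskal"` (rank-based robustness scan; LOD column then holds
#'   -log10 of the Kruskal-Wallis p value).
#' @return An `ecc_qtl_fit` list: `scan`, `threshold`, `peaks` (support
#'   intervals of the peaks above threshold), `method`.
#' @export
scan_qtl <- function(pop, n_perm = ecc_defaults()$n_perm,
                     alpha = ecc_defaults()$alpha, seed,
                     lod_max = ecc_defaults()$lod_max,
                     drop = ecc_defaults()$drop,
                     method = c("regression", "kruskal")) {
  method <- match.arg(method)
  if (method == "regression") {
    scan <- marker_scan(pop, lod_max = lod_max)
  } else {
    scan <- kruskal_scan(pop)
  }
  thr <- permutation_threshold(pop, n_perm = n_perm, alpha = alpha,
                               seed = seed, lod_max = lod_max)
  peaks <- list()
  above <- scan[scan$lod > thr, ]
  for (chr in unique(above$chr)) {
    s <- above[above$chr == chr, ]
    pk <- s$marker[which.max(s$lod)]
    peaks[[length(peaks) + 1L]] <- lod_support_interval(scan, pk,
                                                        drop = drop)
  }
  structure(list(scan = scan,
                 threshold = as.numeric(thr),
                 null_max_lods = attr(thr, "max_lods"),
                 peaks = dplyr::bind_rows(peaks),
                 method = method, alpha = alpha, n_perm = n_perm),
            class = "ecc_qtl_fit")
}

# Rank-based per-marker scan; reported on the -log10(p) scale.
kruskal_scan <- function(pop) {
  lods <- vapply(seq_len(ncol(pop$geno)), function(j) {
    g <- pop$geno[, j]
    keep <- !is.na(g)
    if (length(unique(g[keep])) < 2L) return(0)
    kt <- stats::kruskal.test(pop$phenotype[keep], factor(g[keep]))
    -log10(kt$p.value)
  }, numeric(1))
  out <- tibble::tibble(marker = pop$map$marker, chr = pop$map$chr,
                        pos = pop$map$pos, lod = lods,
                        n = as.integer(colSums(!is.na(pop$geno))),
                        flag = "")
  class(out) <- c("ecc_scan", class(out))
  out
}

#' @export
print.ecc_qtl_fit <- function(x, ...) {
  cat("<ecc_qtl_fit> ", x$method, " scan over ", nrow(x$scan),
      " markers; genome-wide threshold ", round(x$threshold, 2),
      " (alpha ", x$alpha, ", ", x$n_perm, " permutations)\n", sep = "")
  if (nrow(x$peaks) > 0L) {
    cat("  peak(s):\n")
    print(x$peaks)
  } else cat("  no peak above threshold\n")
  invisible(x)
}

#' @export
tidy.ecc_qtl_fit <- function(x, ...) x$scan

#' @export
glance.ecc_qtl_fit <- function(x, ...) {
  tibble::tibble(
    max_lod = max(x$scan$lod),
    threshold = x$threshold,
    n_peaks = nrow(x$peaks),
    n_markers = nrow(x$scan),
    alpha = x$alpha,
    n_perm = x$n_perm
  )
}

#' LOD curve plot for a QTL fit
#'
#' @param object An `ecc_qtl_fit`.
#' @param ... Unused.
#' @return A ggplot: per-chromosome LOD curve with the genome-wide
#'   permutation threshold.
#' @export
autoplot.ecc_qtl_fit <- function(object, ...) {
  ggplot2::ggplot(object$scan,
                  ggplot2::aes(x = .data$pos, y = .data$lod)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$threshold,
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chr),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = "LOD",
                  subtitle = paste0("dashed: genome-wide threshold (alpha ",
                                    object$alpha, ")")) +
    ggplot2::theme_minimal()
}

#' Segregation goodness-of-fit test
#'
#' Pearson chi-square test of observed class counts against an expected
#' ratio (e.g. `c(1, 1)` for the 1:1 segregation of a hemizygous
#' transgene).
#'
#' @param observed Non-negative integer counts per class.
#' @param expected_ratio Positive expected ratio (same length).
#' @return One-row tibble `chi2`, `df`, `p`.
#' @export
#' @examples
#' segregation_test(c(14, 16), c(1, 1))
segregation_test <- function(observed, expected_ratio) {
  if (length(observed) != length(expected_ratio)) {
    stop("Counts and ratio must have the same length.", call. = FALSE)
  }
  if (any(observed < 0) || any(expected_ratio <= 0)) {
    stop("Counts must be >= 0 and the ratio positive.", call. = FALSE)
  }
  if (sum(observed) == 0) stop("Zero total count.", call. = FALSE)
  ct <- suppressWarnings(
    stats::chisq.test(observed, p = expected_ratio / sum(expected_ratio)))
  tibble::tibble(chi2 = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p = ct$p.value)
}
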