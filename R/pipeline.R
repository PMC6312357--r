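#' Build a run configuration
#'
#' All pipeline thresholds with their defaults, input paths and seed,
#' either from arguments or a YAML file ([read_run_config()]). Every
#' threshold default matches [ecc_defaults()].
#'
#' @param fasta Protein FASTA of the receptor panel (required).
#' @param out_dir Output directory.
#' @param seed Integer seed (required: no silent clock seeding).
#' @param matings Optional Y2H mating TSV (enables the network stage).
#' @param phenotypes Optional phenotype TSV.
#' @param geno,map,pheno Optional F2 CSVs (enable the QTL stage).
#' @param ... Threshold overrides (any name from [ecc_defaults()]).
#' @return A `run_config` list.
#' @export
run_config <- function(fasta, out_dir, seed, matings = NULL,
                       phenotypes = NULL, geno = NULL, map = NULL,
                       pheno = NULL, ...) {
  over <- list(...)
  defaults <- ecc_defaults()
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0L) {
    stop("Unknown config option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(over)] <- over
  structure(list(fasta = fasta, out_dir = out_dir, seed = as.integer(seed),
                 matings = matings, phenotypes = phenotypes,
                 geno = geno, map = map, pheno = pheno,
                 thresholds = defaults),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with keys matching the [run_config()] arguments
#'   (thresholds under a `thresholds:` block).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  thr <- y$thresholds %||% list()
  do.call(run_config, c(
    list(fasta = y$fasta, out_dir = y$out_dir, seed = y$seed,
         matings = y$matings, phenotypes = y$phenotypes,
         geno = y$geno, map = y$map, pheno = y$pheno),
    thr))
}

#' Run the pipeline end-to-end
#'
#' annotate -> classify -> (optional) interaction-network statistics ->
#' (optional) QTL scan. Writes GFF3 + TSV annotations, group calls,
#' network edge list and summary, scan results, and a JSON run manifest
#' (package version, config hash, seed, input checksums, and every
#' default that was applied implicitly). Identical config + inputs give
#' identical outputs.
#'
#' @param config A `run_config`.
#' @return The manifest (list), invisibly; outputs land in
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("Pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  inputs <- purrr::compact(config[c("fasta", "matings", "phenotypes",
                                    "geno", "map", "pheno")])
  missing_in <- purrr::keep(inputs, ~ !file.exists(.x))
  if (length(missing_in) > 0L) {
    stop("Missing input file(s): ",
         paste(unlist(missing_in), collapse = ", "), call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  thr <- config$thresholds
  outputs <- character()
  emit <- function(path) outputs <<- c(outputs, path)

  panel <- stage("annotate", read_fasta(config$fasta))
  annotated <- stage("annotate", annotate_panel(
    panel, max_mismatch = thr$max_mismatch, theta_polar = thr$theta_polar))
  emit(write_annotation_gff3(annotated,
                             file.path(config$out_dir, "annotation.gff3")))
  emit(write_annotation_tsv(annotated,
                            file.path(config$out_dir, "annotation.tsv")))

  classified <- stage("classify",
                      classify_panel(annotated, theta_rpw8 = thr$theta_rpw8))
  calls <- attr(classified, "evidence")
  readr::write_tsv(calls, file.path(config$out_dir, "groups.tsv"))
  emit(file.path(config$out_dir, "groups.tsv"))

  if (!is.null(config$matings)) {
    stage("network", {
      matings <- read_matings(config$matings)
      edges <- call_interactions(matings, min_support = thr$min_support)
      net <- ecc_network(edges, nodes = sort(unique(c(matings$bait,
                                                      matings$prey))))
      emit(write_network(net, file.path(config$out_dir, "network.tsv")))
      emit(write_network(net, file.path(config$out_dir, "network.graphml")))
      readr::write_tsv(network_summary(net),
                       file.path(config$out_dir, "network_summary.tsv"))
      emit(file.path(config$out_dir, "network_summary.tsv"))
    })
  }

  if (!is.null(config$geno)) {
    stage("qtl", {
      pop <- read_f2_population(config$geno, config$map, config$pheno)
      fit <- scan_qtl(pop, n_perm = thr$n_perm, alpha = thr$alpha,
                      seed = config$seed, lod_max = thr$lod_max,
                      drop = thr$drop)
      readr::write_tsv(fit$scan, file.path(config$out_dir, "qtl_scan.tsv"))
      emit(file.path(config$out_dir, "qtl_scan.tsv"))
      jsonlite::write_json(
        list(threshold = fit$threshold, peaks = fit$peaks),
        file.path(config$out_dir, "qtl_summary.json"),
        auto_unbox = TRUE, digits = NA)
      emit(file.path(config$out_dir, "qtl_summary.json"))
    })
  }

  manifest <- list(
    package = "ecckit",
    version = as.character(utils::packageVersion("ecckit")),
    seed = config$seed,
    # hash of the analysis-determining part of the config (the output
    # directory does not influence results)
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    thresholds = thr,
    inputs = as.list(tools::md5sum(unname(unlist(inputs)))),
    outputs = basename(outputs)
  )
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
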