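#' Read a protein FASTA into a sequence panel
#'
#' Reads the N-terminal fragment (ECC) sequences of a receptor panel.
#' The token before the first whitespace in each header becomes the `id`;
#' the remainder the `description`. Residues are validated against the
#' 20-letter amino-acid alphabet: ambiguity codes (B/J/O/U/X/Z) and
#' anything else are rejected with the offending record and position.
#'
#' @param path Path to a protein FASTA file.
#' @return A tibble with columns `id`, `residues`, `description`, one row
#'   per entry, in file order. Residue coordinates throughout the package
#'   are 1-based with the initiator Met at position 1.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".faa")
#' writeLines(c(">A demo", "MGGCS"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  aa <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      stop("Malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(aa) == 0L) {
    return(tibble::tibble(id = character(), residues = character(),
                          description = character()))
  }
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  res <- as.character(aa)
  panel <- tibble::tibble(id = ids, residues = unname(res),
                          description = unname(desc))
  validate_panel(panel)
  panel
}

#' Write a sequence panel to FASTA
#'
#' Round-trips with [read_fasta()]: sequences are wrapped at 60 columns.
#'
#' @param records Tibble with columns `id`, `residues` and optionally
#'   `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- as_panel(records)
  validate_panel(records)
  aa <- Biostrings::AAStringSet(records$residues)
  names(aa) <- ifelse(nzchar(records$description),
                      paste(records$id, records$description),
                      records$id)
  Biostrings::writeXStringSet(aa, filepath = path, width = 60L)
  invisible(path)
}

as_panel <- function(records) {
  records <- tibble::as_tibble(records)
  if (!all(c("id", "residues") %in% names(records))) {
    stop("A sequence panel needs columns 'id' and 'residues'.", call. = FALSE)
  }
  if (!"description" %in% names(records)) records$description <- ""
  records$description[is.na(records$description)] <- ""
  records[, c("id", "residues", "description")]
}

validate_panel <- function(panel) {
  dup <- panel$id[duplicated(panel$id)]
  if (length(dup) > 0L) {
    stop("Duplicate sequence id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  purrr::walk2(panel$id, panel$residues, validate_residues)
  invisible(panel)
}

validate_residues <- function(id, residues) {
  if (is.na(residues) || nchar(residues) == 0L) {
    stop("Record '", id, "' has an empty sequence.", call. = FALSE)
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("Record '", id, "': illegal residue '", chars[bad[1]],
         "' at position ", bad[1],
         " (only the 20 standard amino acids are accepted).",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a phenotype table
#'
#' Reads per-ECC ordinal response categories from a TSV with columns
#' `ecc_id`, `species`, `category`. Species are `At` (Arabidopsis,
#' categories 0-6 where 6 is full resistance), `Nb` (N. benthamiana) and
#' `Ls` (lettuce), both scored 0-3. One record per (ecc_id, species).
#'
#' @param path Path to a tab-separated file with a header.
#' @return A tibble `ecc_id`, `species`, `category` (integer).
#' @export
read_phenotypes <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           ecc_id = readr::col_character(),
                           species = readr::col_character(),
                           category = readr::col_integer()
                         ))
  validate_phenotypes(tab)
}

phenotype_scale_max <- c(At = 6L, Nb = 3L, Ls = 3L)

validate_phenotypes <- function(tab) {
  tab <- tibble::as_tibble(tab)
  need <- c("ecc_id", "species", "category")
  if (!all(need %in% names(tab))) {
    stop("Phenotype table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad_sp <- setdiff(unique(tab$species), names(phenotype_scale_max))
  if (length(bad_sp) > 0L) {
    stop("Unknown species: ", paste(bad_sp, collapse = ", "),
         " (expected At, Nb, Ls).", call. = FALSE)
  }
  hi <- phenotype_scale_max[tab$species]
  out <- which(is.na(tab$category) | tab$category < 0L | tab$category > hi)
  if (length(out) > 0L) {
    i <- out[1]
    stop("Phenotype category out of range for '", tab$ecc_id[i], "' (",
         tab$species[i], "): got ", tab$category[i], ", scale is 0-",
         phenotype_scale_max[[tab$species[i]]], ".", call. = FALSE)
  }
  key <- paste(tab$ecc_id, tab$species)
  if (anyDuplicated(key)) {
    stop("Duplicate phenotype record(s) for: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  tab[, need]
}

#' Read an aligned FASTA block
#'
#' Reads a multiple alignment (gap character `-` only; `.` is rejected)
#' into an aligned block tibble. All rows must have equal length.
#'
#' @param path Path to an aligned FASTA.
#' @return A tibble with columns `id` and `aligned` plus attribute
#'   `ncol` (alignment width).
#' @export
read_alignment <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  rows <- as.character(aa)
  block <- tibble::tibble(id = ids, aligned = unname(rows))
  validate_alignment(block)
}

validate_alignment <- function(block) {
  block <- tibble::as_tibble(block)
  if (!all(c("id", "aligned") %in% names(block))) {
    stop("An aligned block needs columns 'id' and 'aligned'.", call. = FALSE)
  }
  w <- unique(nchar(block$aligned))
  if (length(w) > 1L) {
    stop("Alignment rows have unequal lengths: ",
         paste(w, collapse = ", "), call. = FALSE)
  }
  if (any(grepl(".", block$aligned, fixed = TRUE))) {
    stop("Alignment uses '.' gaps; only '-' is accepted.", call. = FALSE)
  }
  bad <- grepl(paste0("[^-", paste(AA_ALPHABET, collapse = ""), "]"),
               block$aligned)
  if (any(bad)) {
    stop("Alignment row '", block$id[which(bad)[1]],
         "' contains characters outside the amino-acid alphabet plus '-'.",
         call. = FALSE)
  }
  attr(block, "ncol") <- if (nrow(block)) w else 0L
  block
}

#' Remove gaps from an aligned row
#' @param aligned Aligned string with `-` gaps.
#' @return Ungapped string.
#' @export
ungap <- function(aligned) gsub("-", "", aligned, fixed = TRUE)
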