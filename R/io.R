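# ---- readers/writers for the canonical table formats ----

.peptide_cols <- c("protein_id", "peptide", "start", "end", "mod",
                   "condition", "replicate", "intensity", "spectral_count")

# parse "none" / "ox:<pos>" tokens; returns integer positions (NA for none)
parse_mod_tokens <- function(mod, start, end, lines = seq_along(mod)) {
  pos <- rep(NA_integer_, length(mod))
  is_ox <- grepl("^ox2?:", mod)
  bad <- !(mod == "none" | grepl("^ox2?:[0-9]+$", mod))
  if (any(bad)) {
    abort_aaplr(sprintf("invalid mod token '%s' at line %d",
                        mod[which(bad)[1]], lines[which(bad)[1]]),
                "aaplr_parse_error")
  }
  pos[is_ox] <- as.integer(sub("^ox2?:", "", mod[is_ox]))
  out_of_pep <- is_ox & (pos < start | pos > end | pos < 1L)
  if (any(out_of_pep)) {
    i <- which(out_of_pep)[1]
    abort_aaplr(sprintf(
      "mod '%s' at line %d: oxidized position outside peptide [%d, %d]",
      mod[i], lines[i], start[i], end[i]), "aaplr_parse_error")
  }
  pos
}

#' Read a peptide-level quantification table
#'
#' Reads the canonical tab-separated peptide measurement table (one row per
#' peptidoform x condition x replicate). Every row is validated: `start <=
#' end`, oxidized positions inside the peptide, non-negative intensity and
#' spectral count. Rows with both intensity 0 and spectral count 0 carry no
#' evidence and are dropped (the count is reported via `message()`).
#'
#' @param path Path to a TSV file with header columns `protein_id`,
#'   `peptide`, `start`, `end`, `mod`, `condition`, `replicate`,
#'   `intensity`, `spectral_count`.
#' @return Data frame of validated peptide measurements.
#' @seealso [write_peptide_table()], [simulate_experiment()]
#' @export
read_peptide_table <- function(path) {
  if (!file.exists(path)) {
    abort_aaplr(sprintf("file not found: %s", path), "aaplr_io_error")
  }
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  assert_columns(x, .peptide_cols, sprintf("peptide table '%s'", path))
  x <- x[, .peptide_cols]
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x$replicate <- as.integer(x$replicate)
  x$condition <- as.character(x$condition)
  x$mod <- as.character(x$mod)
  if (any(x$start > x$end)) {
    abort_aaplr("peptide table has rows with start > end", "aaplr_parse_error")
  }
  if (any(x$intensity < 0) || any(x$spectral_count < 0)) {
    abort_aaplr("negative intensity or spectral_count", "aaplr_parse_error")
  }
  parse_mod_tokens(x$mod, x$start, x$end, lines = seq_len(nrow(x)) + 1L)
  empty <- x$intensity == 0 & x$spectral_count == 0
  if (any(empty)) {
    message(sprintf("read_peptide_table: dropped %d evidence-free row(s)",
                    sum(empty)))
    x <- x[!empty, ]
  }
  rownames(x) <- NULL
  x
}

#' Write a peptide-level quantification table
#'
#' @param x Data frame of peptide measurements (columns as documented in
#'   [read_peptide_table()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(x, path) {
  assert_columns(x, .peptide_cols, "peptide table")
  write.table(x[, .peptide_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a STRING-style protein links file
#'
#' Accepts both the STRING download dialect (integer combined scores,
#' 0-1000) and already-normalized real scores in \[0, 1\]; integer scores
#' are divided by 1000. Duplicate unordered pairs are collapsed keeping the
#' maximum score; edges below `score_floor` are dropped.
#'
#' @param path TSV (or whitespace-separated) file whose first three columns
#'   are protein a, protein b, combined score. Headers named
#'   `protein1`/`protein2`/`combined_score` or
#'   `protein_a`/`protein_b`/`combined_score` are both accepted.
#' @param score_floor Minimum retained combined score on the \[0, 1\] scale
#'   (default 0.4, the conventional medium-confidence floor).
#' @return Data frame with columns `protein_a`, `protein_b`,
#'   `combined_score` (in \[0, 1\]), one row per unordered pair.
#' @export
read_string_links <- function(path, score_floor = 0.4) {
  if (!file.exists(path)) {
    abort_aaplr(sprintf("file not found: %s", path), "aaplr_io_error")
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ""
  x <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (ncol(x) < 3) {
    abort_aaplr("STRING links file needs two id columns and a score column",
                "aaplr_schema_error")
  }
  x <- x[, 1:3]
  names(x) <- c("protein_a", "protein_b", "combined_score")
  s <- x$combined_score
  if (!is.numeric(s) || anyNA(s)) {
    abort_aaplr("combined_score must be numeric", "aaplr_parse_error")
  }
  if (any(s < 0) || any(s > 1000)) {
    abort_aaplr("combined_score outside [0, 1000]", "aaplr_parse_error")
  }
  if (any(s > 1)) s <- s / 1000           # STRING integer dialect
  x$combined_score <- s
  x <- x[x$protein_a != x$protein_b, ]
  key <- pair_key(x$protein_a, x$protein_b)
  x <- x[order(key, -x$combined_score), ]
  x <- x[!duplicated(pair_key(x$protein_a, x$protein_b)), ]
  x <- x[x$combined_score >= score_floor, ]
  rownames(x) <- NULL
  x
}

#' Write edges in the STRING links dialect (integer scores 0-1000)
#'
#' @param edges Data frame with `protein_a`, `protein_b`, `combined_score`
#'   in \[0, 1\].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_string_links <- function(edges, path) {
  assert_columns(edges, c("protein_a", "protein_b", "combined_score"),
                 "edge table")
  out <- data.frame(protein1 = edges$protein_a, protein2 = edges$protein_b,
                    combined_score = as.integer(round(
                      edges$combined_score * 1000)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a region annotation table
#'
#' Regions (extracellular stretches, named domains, topological segments)
#' are given as 1-based inclusive residue intervals; regions may overlap.
#'
#' @param path TSV with columns `protein_id`, `region_name`, `start`, `end`.
#' @return Validated data frame.
#' @export
read_region_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  assert_columns(x, c("protein_id", "region_name", "start", "end"),
                 sprintf("region table '%s'", path))
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (any(x$start > x$end) || any(x$start < 1L)) {
    abort_aaplr("region table has invalid intervals", "aaplr_parse_error")
  }
  x
}

#' Read a glycopeptide composition table
#'
#' @param path TSV with columns `protein_id`, `site`, `Hex`, `HexNAc`,
#'   `Fuc`, `NeuAc`, `intensity`.
#' @return Validated data frame (composition counts as integers).
#' @export
read_glyco_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  assert_columns(x, c("protein_id", "site", "Hex", "HexNAc", "Fuc", "NeuAc",
                      "intensity"), sprintf("glycopeptide table '%s'", path))
  for (cc in c("Hex", "HexNAc", "Fuc", "NeuAc")) {
    x[[cc]] <- as.integer(x[[cc]])
    if (any(x[[cc]] < 0)) {
      abort_aaplr(sprintf("negative %s count in glycopeptide table", cc),
                  "aaplr_parse_error")
    }
  }
  if (any(x$intensity < 0)) {
    abort_aaplr("negative intensity in glycopeptide table", "aaplr_parse_error")
  }
  x
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Data frame with columns `protein_id` (first word of the header)
#'   and `sequence`.
#' @export
read_fasta_proteome <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort_aaplr("reading FASTA requires the Biostrings package",
                "aaplr_io_error")
  }
  ss <- Biostrings::readAAStringSet(path)
  data.frame(
    protein_id = vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L),
    sequence = as.character(ss),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write result tables to a directory
#'
#' Writes each element of a named list of data frames as
#' `<out_dir>/<name>.tsv` with a fixed column order (the data frame's own).
#' Re-running with identical inputs produces byte-identical files.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if absent).
#' @return Data frame manifest with columns `name`, `path`, `n_rows`.
#' @export
write_results <- function(tables, out_dir) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    abort_aaplr("tables must be a fully named list", "aaplr_invalid_parameter")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort_aaplr(sprintf("cannot create output directory '%s'", out_dir),
                "aaplr_io_error")
  }
  paths <- character(length(tables))
  for (i in seq_along(tables)) {
    paths[i] <- file.path(out_dir, paste0(names(tables)[i], ".tsv"))
    write.table(tables[[i]], paths[i], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  data.frame(name = names(tables), path = paths,
             n_rows = vapply(tables, nrow, integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}
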