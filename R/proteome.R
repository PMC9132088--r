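# ---- synthetic proteome and in-silico tryptic digestion ----

#' Generate a synthetic proteome
#'
#' Draws `n_proteins` random protein sequences from a fixed amino-acid
#' frequency table (average Swiss-Prot composition), with lognormal lengths
#' (mean `mean_protein_length`, floor 30 residues). Stands in for the
#' membrane-enriched proteome of a cultured cell line.
#'
#' @param params An [sim_params()] object; uses `n_proteins`,
#'   `mean_protein_length`, and `seed`.
#' @return Data frame with columns `protein_id` (unique, `SYN0001`-style)
#'   and `sequence`.
#' @examples
#' generate_proteome(sim_params(n_proteins = 3, seed = 7))$protein_id
#' @export
generate_proteome <- function(params) {
  if (!inherits(params, "aapl_sim_params")) {
    abort_aaplr("params must be created with sim_params()",
                "aaplr_invalid_parameter")
  }
  n <- params$n_proteins
  aa <- names(.aa_frequencies)
  prob <- .aa_frequencies / sum(.aa_frequencies)
  withr::with_seed(params$seed, {
    lens <- pmax(30L, as.integer(round(
      rlnorm(n, meanlog = log(params$mean_protein_length), sdlog = 0.35))))
    seqs <- vapply(lens, function(L) {
      paste(sample(aa, L, replace = TRUE, prob = prob), collapse = "")
    }, character(1))
  })
  data.frame(
    protein_id = sprintf("SYN%04d", seq_len(n)),
    sequence = seqs,
    stringsAsFactors = FALSE
  )
}

#' In-silico tryptic digestion of one protein sequence
#'
#' Cleaves C-terminal to lysine (K) or arginine (R) except when the next
#' residue is proline (P). Fully cleaved fragments are returned together
#' with all products carrying up to `missed_cleavages` internal missed
#' sites. Peptides outside the detectability window
#' \[`min_len`, `max_len`\] are dropped.
#'
#' @param sequence Amino-acid string (uppercase).
#' @param missed_cleavages Maximum number of missed cleavage sites (>= 0).
#' @param min_len,max_len Peptide length detectability window (residues).
#' @return Data frame with columns `peptide`, `start`, `end` (1-based
#'   inclusive residue coordinates in the protein).
#' @examples
#' digest_protein("AAAKAAARCCCCCC")           # only CCCCCC survives the filter
#' digest_protein("AAAKAAARCCCCCC", min_len = 1)
#' @export
digest_protein <- function(sequence, missed_cleavages = 0,
                           min_len = 6, max_len = 50) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    abort_aaplr("sequence must be a single non-empty string",
                "aaplr_invalid_parameter")
  }
  assert_scalar_number(missed_cleavages, "missed_cleavages", min = 0,
                       integerish = TRUE)
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  # cleavage after position i: K/R at i, and residue i+1 is not P
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after == L | res[pmin(cut_after + 1L, L)] != "P"]
  bounds <- c(0L, cut_after[cut_after < L], L)  # fragment boundaries
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  nfrag <- length(starts)

  out_start <- integer(0)
  out_end <- integer(0)
  for (mc in 0:min(missed_cleavages, nfrag - 1L)) {
    i <- seq_len(nfrag - mc)
    out_start <- c(out_start, starts[i])
    out_end <- c(out_end, ends[i + mc])
  }
  len <- out_end - out_start + 1L
  keep <- len >= min_len & len <= max_len
  out_start <- out_start[keep]
  out_end <- out_end[keep]
  data.frame(
    peptide = substring(sequence, out_start, out_end),
    start = out_start,
    end = out_end,
    stringsAsFactors = FALSE
  )
}

# Digest every protein of a proteome; returns one row per peptide with
# protein_id, peptide, start, end.
digest_proteome <- function(proteome, params) {
  pieces <- lapply(seq_len(nrow(proteome)), function(i) {
    d <- digest_protein(proteome$sequence[i],
                        missed_cleavages = params$missed_cleavages,
                        min_len = params$peptide_min_len,
                        max_len = params$peptide_max_len)
    if (nrow(d)) d$protein_id <- proteome$protein_id[i]
    d
  })
  out <- do.call(rbind, pieces[vapply(pieces, nrow, 1L) > 0])
  out[, c("protein_id", "peptide", "start", "end")]
}
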