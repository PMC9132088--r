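# shared fixture builders; everything is generated in code at test time

# hand-sized measurement table: one protein, two peptides, one condition
tiny_measurements <- function() {
  data.frame(
    protein_id = "P1",
    peptide = c("SAMPLEK", "SAMPLEK", "AAAGGGR"),
    start = c(40L, 40L, 60L),
    end = c(46L, 46L, 66L),
    mod = c("none", "ox:42", "none"),
    condition = "M5",
    replicate = 1L,
    intensity = c(8e6, 2e6, 1e7),
    spectral_count = c(8L, 2L, 10L),
    stringsAsFactors = FALSE
  )
}

# random peptide measurement table for property tests: one protein, one
# condition, <= max_pep peptides, random oxidized forms
random_peptide_table <- function(max_pep = 20) {
  n_pep <- sample(1:max_pep, 1)
  len <- sample(6:20, n_pep, replace = TRUE)
  start <- sample(1:500, n_pep, replace = TRUE)
  pep <- vapply(len, function(L) {
    paste(sample(LETTERS[1:20], L, replace = TRUE), collapse = "")
  }, character(1))
  n_ox <- sample(0:3, n_pep, replace = TRUE)
  idx <- rep.int(seq_len(n_pep), 1L + n_ox)      # one unmod row + ox rows
  is_unmod <- !duplicated(idx)
  off <- unlist(lapply(seq_len(n_pep), function(i) {
    if (n_ox[i]) c(NA, sample.int(len[i], n_ox[i])) else NA
  }), use.names = FALSE)
  n <- length(idx)
  data.frame(
    protein_id = "P1",
    peptide = pep[idx], start = start[idx], end = start[idx] + len[idx] - 1L,
    mod = ifelse(is_unmod, "none", paste0("ox:", start[idx] + off - 1L)),
    condition = "M5", replicate = 1L,
    intensity = runif(n, 0, 1e7),
    spectral_count = sample(0:20, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# brute-force oracles, independent of the package internals
oracle_epo <- function(x) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(x))) {
    den <- den + x$intensity[i]
    if (x$mod[i] != "none") num <- num + x$intensity[i]
  }
  if (den == 0) NA_real_ else num / den
}

oracle_site_degree <- function(x) {
  # x: rows of one peptide+condition; returns named degree vector
  total <- sum(x$intensity)
  ox <- x[x$mod != "none", , drop = FALSE]
  if (!nrow(ox) || total <= 0) return(numeric(0))
  pos <- sub("^ox:", "", ox$mod)
  out <- tapply(ox$intensity, pos, sum) / total
  out <- out[order(as.integer(names(out)))]
  setNames(as.numeric(out), names(out))
}

oracle_tops <- function(m) {
  out <- matrix(0, nrow(m), ncol(m))
  total <- sum(m)
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      v <- m[i, j]
      if (v > 0) {
        e <- sum(m[i, ]) * sum(m[, j]) / total
        out[i, j] <- v * log(v / e)
      }
    }
  }
  out
}

# small cached simulation shared by several test files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_aapl_experiment(
        sim_params(n_proteins = 40, n_proximal = 5, seed = 11),
        experiment_design(treatments = c("M1", "M2", "M3"), selected = "M3",
                          controls = c("C1", "C2"), replicates = 3),
        overlap_fraction = 0.6, n_decoy_edges = 15)
    }
    cache
  }
})
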