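# ---- TopS-adapted AAPL interaction scoring ----

#' Build the proteins x conditions score matrix
#'
#' The AAPL score combines the two protein-level oxidation readouts: each
#' matrix entry is the oxidized spectral count of the protein in that
#' condition multiplied by its EPO (mode `"spc_epo"`, the default), or the
#' oxidized spectral count alone (mode `"spc"`). Rows that are zero across
#' all conditions carry no oxidation evidence and are dropped (reported
#' via `message()`).
#'
#' @param profiles Output of [oxidation_profiles()].
#' @param mode Entry composition rule, `"spc_epo"` or `"spc"`.
#' @return Numeric matrix (proteins x conditions) with non-negative
#'   entries.
#' @export
build_score_matrix <- function(profiles, mode = c("spc_epo", "spc")) {
  mode <- match.arg(mode)
  assert_columns(profiles, c("protein_id", "condition", "epo",
                             "ox_spectral_count"), "profiles")
  prots <- sort(unique(profiles$protein_id))
  conds <- sort(unique(profiles$condition))
  m <- matrix(0, nrow = length(prots), ncol = length(conds),
              dimnames = list(prots, conds))
  epo <- ifelse(is.na(profiles$epo), 0, profiles$epo)
  v <- switch(mode,
              spc_epo = profiles$ox_spectral_count * epo,
              spc = as.numeric(profiles$ox_spectral_count))
  m[cbind(match(profiles$protein_id, prots),
          match(profiles$condition, conds))] <- v
  zero <- rowSums(m) == 0
  if (any(zero)) {
    message(sprintf("build_score_matrix: dropped %d all-zero protein row(s)",
                    sum(zero)))
    m <- m[!zero, , drop = FALSE]
  }
  if (!nrow(m)) {
    abort_aaplr("score matrix is empty after dropping all-zero rows",
                "aaplr_pipeline_error")
  }
  m
}

#' Topological scores (TopS) of a non-negative matrix
#'
#' For a matrix of observed values `v(p, c)` with row sums `R_p`, column
#' sums `C_c`, and grand total `T`, the expectation under row/column
#' independence is `E(p, c) = R_p * C_c / T` and the topological score is
#' `v * ln(v / E)` where `v > 0`, and 0 where `v = 0`. A score is positive
#' exactly when the observed value exceeds its expectation, so proteins
#' oxidized preferentially in one condition score positive there.
#'
#' @param m Non-negative numeric matrix with a positive grand total.
#' @return Matrix of the same shape with the TopS transform applied.
#' @examples
#' tops(matrix(c(20, 10, 10, 10), 2, byrow = TRUE))[1, 1]  # 20*log(20/18)
#' @export
tops <- function(m) {
  if (!is.matrix(m) || !is.numeric(m) || any(m < 0) || anyNA(m)) {
    abort_aaplr("tops() needs a non-negative numeric matrix",
                "aaplr_invalid_parameter")
  }
  total <- sum(m)
  if (total <= 0) {
    abort_aaplr("tops() needs a matrix with positive grand total",
                "aaplr_invalid_parameter")
  }
  e <- outer(rowSums(m), colSums(m)) / total
  s <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  pos <- m > 0
  s[pos] <- m[pos] * log(m[pos] / e[pos])
  s
}

#' AAPL interaction scores at the selected condition
#'
#' Computes the TopS transform of the score matrix across all treatment
#' and control conditions and reads each protein's score in the selected
#' (optimal) treatment condition; the other columns participate only
#' through the row/column expectations. Proteins with zero entry in the
#' selected condition score 0.
#'
#' @param profiles Output of [oxidation_profiles()].
#' @param design An [experiment_design()]; its `selected` condition is
#'   scored.
#' @param mode Matrix composition rule, see [build_score_matrix()];
#'   `"tops_epo"` applies TopS to spectral counts alone and multiplies the
#'   selected-condition score by the EPO afterwards.
#' @param rescale_total Optional positive number: rescale the matrix to
#'   this fixed grand total before the transform, decoupling score
#'   magnitude from sequencing depth (`NULL`, the default, scores raw
#'   values so the conventional 0/1 thresholds apply at comparable depth).
#' @return Data frame with `protein_id`, `aapl_score`,
#'   `selected_condition`.
#' @export
aapl_scores <- function(profiles, design, mode = c("spc_epo", "spc",
                                                   "tops_epo"),
                        rescale_total = NULL) {
  mode <- match.arg(mode)
  if (!inherits(design, "aapl_design")) {
    abort_aaplr("design must be created with experiment_design()",
                "aaplr_invalid_parameter")
  }
  m <- build_score_matrix(profiles,
                          mode = if (mode == "tops_epo") "spc" else mode)
  if (!design$selected %in% colnames(m)) {
    abort_aaplr(sprintf("selected condition '%s' is absent from the data",
                        design$selected), "aaplr_config_error")
  }
  if (!is.null(rescale_total)) {
    assert_scalar_number(rescale_total, "rescale_total", min = 1e-12)
    m <- m * (rescale_total / sum(m))
  }
  s <- tops(m)[, design$selected]
  if (mode == "tops_epo") {
    sel <- profiles[profiles$condition == design$selected, ]
    epo <- setNames(ifelse(is.na(sel$epo), 0, sel$epo), sel$protein_id)
    s <- s * ifelse(is.na(epo[names(s)]), 0, epo[names(s)])
  }
  data.frame(protein_id = names(s), aapl_score = as.vector(s),
             selected_condition = design$selected,
             stringsAsFactors = FALSE, row.names = NULL)
}
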