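# ---- interactor levels, STRING types, summary statistics ----

#' Call L1/L2 interactor levels from AAPL scores and EPO fold changes
#'
#' Level 1 (L1) interactors have an AAPL score strictly above 1. Level 2
#' (L2) interactors have a score in (0, 1] together with an EPO fold
#' change strictly above 1.5. Everything else (including proteins without
#' a defined fold change) is `"none"`. The bait itself is excluded from
#' the result. Boundary convention: "above" is strict, so score exactly 1
#' is not L1 and fold change exactly 1.5 is not L2; score exactly 0 is not
#' L2.
#'
#' @param scores Data frame with `protein_id`, `aapl_score` (one row per
#'   protein; duplicates are an error).
#' @param fold_changes Data frame with `protein_id`, `epo_fc` at the
#'   scored condition.
#' @param bait_id Bait protein id (excluded).
#' @param l1_threshold,l2_fc_threshold Printed rule thresholds (defaults 1
#'   and 1.5).
#' @return Data frame with `protein_id`, `aapl_score`, `epo_fc`, `level`
#'   (`"L1"`, `"L2"`, or `"none"`).
#' @export
classify_levels <- function(scores, fold_changes, bait_id,
                            l1_threshold = 1, l2_fc_threshold = 1.5) {
  assert_columns(scores, c("protein_id", "aapl_score"), "scores")
  assert_columns(fold_changes, c("protein_id", "epo_fc"), "fold_changes")
  if (anyDuplicated(scores$protein_id) ||
      anyDuplicated(fold_changes$protein_id)) {
    abort_aaplr("duplicate protein ids in scores or fold changes",
                "aaplr_input_error")
  }
  x <- scores[scores$protein_id != bait_id, c("protein_id", "aapl_score")]
  x$epo_fc <- fold_changes$epo_fc[match(x$protein_id,
                                        fold_changes$protein_id)]
  s <- x$aapl_score
  fc <- x$epo_fc
  x$level <- ifelse(s > l1_threshold, "L1",
             ifelse(s > 0 & s <= l1_threshold & !is.na(fc) &
                    fc > l2_fc_threshold, "L2", "none"))
  rownames(x) <- NULL
  x
}

#' STRING interactor typing (T1-T4)
#'
#' Types every classified protein against known-interaction evidence:
#' \itemize{
#'   \item T1 - direct bait edge with combined score above 0.7 (high
#'     confidence);
#'   \item T2 - direct bait edge with score in \[0.4, 0.7\] (medium);
#'   \item T3 - no qualifying direct bait edge, but an edge (score >= 0.4)
#'     to some T1 or T2 protein (secondary interactor);
#'   \item T4 - the remaining proteins.
#' }
#'
#' @param protein_ids Character vector of proteins to type (the oxidized,
#'   scored universe; bait excluded by the caller).
#' @param edges Edge table with `protein_a`, `protein_b`,
#'   `combined_score` in \[0, 1\].
#' @param bait_id Bait protein id.
#' @param high,low Confidence cut points (defaults 0.7 and 0.4).
#' @return Character vector of types, parallel to `protein_ids`.
#' @export
string_types <- function(protein_ids, edges, bait_id, high = 0.7, low = 0.4) {
  assert_columns(edges, c("protein_a", "protein_b", "combined_score"),
                 "edges")
  if (nrow(edges) && (any(edges$combined_score < 0) ||
                      any(edges$combined_score > 1))) {
    abort_aaplr("edge scores must be normalized to [0, 1]",
                "aaplr_invalid_parameter")
  }
  bait_score <- function(p) {
    hit <- (edges$protein_a == bait_id & edges$protein_b == p) |
           (edges$protein_b == bait_id & edges$protein_a == p)
    if (any(hit)) max(edges$combined_score[hit]) else NA_real_
  }
  bs <- vapply(protein_ids, bait_score, numeric(1))
  type <- ifelse(!is.na(bs) & bs > high, "T1",
          ifelse(!is.na(bs) & bs >= low, "T2", NA_character_))
  t12 <- protein_ids[!is.na(type)]
  for (i in which(is.na(type))) {
    p <- protein_ids[i]
    nb <- (edges$protein_a == p & edges$protein_b %in% t12) |
          (edges$protein_b == p & edges$protein_a %in% t12)
    type[i] <- if (any(nb & edges$combined_score >= low)) "T3" else "T4"
  }
  unname(type)
}

#' Classify interactors: levels, STRING types, site counts
#'
#' The end-to-end classification step: joins AAPL scores with EPO fold
#' changes and oxidation-site counts at the selected condition, calls
#' L1/L2 levels, and types every protein against the STRING edges.
#'
#' @param profiles Output of [oxidation_profiles()].
#' @param scores Output of [aapl_scores()].
#' @param edges Normalized edge table.
#' @param bait_id Bait protein id.
#' @param design An [experiment_design()].
#' @param l1_threshold,l2_fc_threshold,string_high,string_low Rule
#'   thresholds.
#' @return Data frame with `protein_id`, `aapl_score`, `epo_fc`, `level`,
#'   `string_type`, `n_sites`.
#' @export
classify_interactors <- function(profiles, scores, edges, bait_id, design,
                                 l1_threshold = 1, l2_fc_threshold = 1.5,
                                 string_high = 0.7, string_low = 0.4) {
  sel <- profiles[profiles$condition == design$selected, ]
  fc <- sel[, c("protein_id", "epo_fc")]
  res <- classify_levels(scores, fc, bait_id,
                         l1_threshold = l1_threshold,
                         l2_fc_threshold = l2_fc_threshold)
  res$string_type <- string_types(res$protein_id, edges, bait_id,
                                  high = string_high, low = string_low)
  res$n_sites <- sel$n_sites[match(res$protein_id, sel$protein_id)]
  res$n_sites[is.na(res$n_sites)] <- 0L
  res
}

#' Mean oxidation-site counts by AAPL score bin
#'
#' Averages the number of oxidation sites over the score bins
#' `(1, Inf)`, `(0, 1]`, and `(-Inf, 0]` (score exactly 0 falls in the
#' lowest bin).
#'
#' @param results Output of [classify_interactors()] (needs `aapl_score`,
#'   `n_sites`).
#' @return Data frame with `bin`, `n_proteins`, `mean_sites` (`NaN` for
#'   empty bins).
#' @export
mean_sites_by_score_bin <- function(results) {
  assert_columns(results, c("aapl_score", "n_sites"), "results")
  bins <- list(`score>1` = results$aapl_score > 1,
               `0<score<=1` = results$aapl_score > 0 & results$aapl_score <= 1,
               `score<=0` = results$aapl_score <= 0)
  data.frame(
    bin = names(bins),
    n_proteins = vapply(bins, sum, integer(1)),
    mean_sites = vapply(bins, function(i) {
      if (!any(i)) NaN else mean(results$n_sites[i])
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' AAPL score distribution of known (T1/T2) interactors
#'
#' Among proteins typed T1 or T2, the fractions with AAPL score above 1,
#' in (0, 1], and at or below 0. The three fractions sum to 1.
#'
#' @param results Output of [classify_interactors()].
#' @return Named numeric vector `c(above_1, between_0_1, below_0)`, or
#'   `NULL` when there are no T1/T2 proteins.
#' @export
score_distribution_known <- function(results) {
  assert_columns(results, c("aapl_score", "string_type"), "results")
  known <- results[results$string_type %in% c("T1", "T2"), ]
  if (!nrow(known)) return(NULL)
  s <- known$aapl_score
  c(above_1 = mean(s > 1),
    between_0_1 = mean(s > 0 & s <= 1),
    below_0 = mean(s <= 0))
}

#' Cross-reactivity report for an off-target antigen
#'
#' When data acquired with antibody B is analyzed, a specific antibody
#' should not oxidize an unrelated antigen A: A's EPO fold change should
#' stay low and A should not be called an L1/L2 interactor of B. This
#' report extracts A's call and flags cross-reactivity when A would
#' classify as an interactor.
#'
#' @param results Output of [classify_interactors()] computed on
#'   antibody-B data.
#' @param off_target_id Protein id of the unrelated antigen A.
#' @return One-row data frame with `protein_id`, `detected`, `aapl_score`,
#'   `epo_fc`, `level`, `flagged`.
#' @export
cross_reactivity_report <- function(results, off_target_id) {
  i <- match(off_target_id, results$protein_id)
  if (is.na(i)) {
    return(data.frame(protein_id = off_target_id, detected = FALSE,
                      aapl_score = NA_real_, epo_fc = NA_real_,
                      level = "not detected", flagged = FALSE,
                      stringsAsFactors = FALSE))
  }
  data.frame(protein_id = off_target_id, detected = TRUE,
             aapl_score = results$aapl_score[i],
             epo_fc = results$epo_fc[i],
             level = results$level[i],
             flagged = results$level[i] %in% c("L1", "L2"),
             stringsAsFactors = FALSE)
}
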