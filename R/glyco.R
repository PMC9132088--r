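# ---- glycan typing and glycosylation-stratified comparisons ----

.glyco_types <- c("CH", "F", "FS", "HM", "S")

#' Classify an N-glycan composition into the five canonical types
#'
#' Rule table over monosaccharide counts (vectorized):
#' \itemize{
#'   \item HM (high mannose): HexNAc <= 2, Hex >= 4, no Fuc, no NeuAc;
#'   \item FS (fucosyl-sialylated): at least one Fuc and one NeuAc;
#'   \item F (fucosylated): at least one Fuc (no NeuAc);
#'   \item S (sialylated): at least one NeuAc (no Fuc);
#'   \item CH (neutral complex/hybrid): everything else.
#' }
#' FS takes precedence over F and S; HM is checked first, matching the
#' standard Hex4-9HexNAc2 unsubstituted high-mannose definition.
#'
#' @param hex,hexnac,fuc,neuac Non-negative integer monosaccharide counts
#'   (recycled to a common length).
#' @return Character vector of types in `c("CH", "F", "FS", "HM", "S")`.
#' @examples
#' classify_glycan(9, 2, 0, 0)  # "HM"
#' classify_glycan(5, 4, 1, 2)  # "FS"
#' classify_glycan(5, 4, 0, 0)  # "CH"
#' @export
classify_glycan <- function(hex, hexnac, fuc, neuac) {
  n <- max(length(hex), length(hexnac), length(fuc), length(neuac))
  hex <- rep_len(hex, n); hexnac <- rep_len(hexnac, n)
  fuc <- rep_len(fuc, n); neuac <- rep_len(neuac, n)
  counts <- cbind(hex, hexnac, fuc, neuac)
  if (anyNA(counts) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    abort_aaplr("glycan composition counts must be non-negative integers",
                "aaplr_input_error")
  }
  ifelse(hexnac <= 2 & hex >= 4 & fuc == 0 & neuac == 0, "HM",
  ifelse(fuc >= 1 & neuac >= 1, "FS",
  ifelse(fuc >= 1, "F",
  ifelse(neuac >= 1, "S", "CH"))))
}

#' Per-protein glycan-type summary
#'
#' Totals and percentages of the five glycan types for one protein (or the
#' whole table), weighted by glycopeptide intensity (default) or by
#' glycopeptide count.
#'
#' @param records Glycopeptide table with `protein_id`, `Hex`, `HexNAc`,
#'   `Fuc`, `NeuAc`, `intensity` (see [read_glyco_table()]).
#' @param protein_id Optional single protein id to restrict to.
#' @param weight `"intensity"` (default) or `"count"`.
#' @return Data frame with one row per glycan type: `glyco_type`, `total`,
#'   `percent` (percentages sum to 100). `NULL` when the restriction
#'   matches nothing; zero total weight is an error.
#' @export
glyco_summary <- function(records, protein_id = NULL,
                          weight = c("intensity", "count")) {
  weight <- match.arg(weight)
  assert_columns(records, c("protein_id", "Hex", "HexNAc", "Fuc", "NeuAc",
                            "intensity"), "glycopeptide table")
  if (!is.null(protein_id)) {
    records <- records[records$protein_id == protein_id, , drop = FALSE]
  }
  if (!nrow(records)) return(NULL)
  type <- classify_glycan(records$Hex, records$HexNAc, records$Fuc,
                          records$NeuAc)
  w <- if (weight == "intensity") records$intensity else rep(1, nrow(records))
  tot <- vapply(.glyco_types, function(t) sum0(w[type == t]), numeric(1))
  grand <- sum(tot)
  if (grand <= 0) {
    abort_aaplr("zero total weight: cannot form glycan percentages",
                "aaplr_input_error")
  }
  data.frame(glyco_type = .glyco_types, total = unname(tot),
             percent = unname(100 * tot / grand),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Dominant glycan type of a protein
#'
#' @inheritParams glyco_summary
#' @return The glycan type with the largest total weight (ties broken
#'   alphabetically), or `NA` when the protein has no records.
#' @export
dominant_glyco_type <- function(records, protein_id = NULL,
                                weight = c("intensity", "count")) {
  s <- glyco_summary(records, protein_id = protein_id, weight = weight)
  if (is.null(s)) return(NA_character_)
  s$glyco_type[which.max(s$total)]
}

#' Compare interactor oxidation across glycosylation-inhibitor conditions
#'
#' Contrasts each glycosylated interactor's EPO under the optimal AAPL
#' condition (`AAPL-ctrl`) against the same labeling performed after
#' kifunensine (`AAPL-Kif`, blocks complex/hybrid glycan maturation) or a
#' sialyltransferase inhibitor (`AAPL-SI`, strips sialylation). A protein
#' whose EPO ratio to the control drops below `1 - delta` is flagged as
#' decreased - evidence that its interaction with the bait depends on the
#' perturbed glycan class. The protein's dominant glycan type is attached
#' for the sialylated-vs-high-mannose contrast.
#'
#' @param profiles Data frame with `protein_id`, `condition`, `epo`
#'   covering the three inhibitor-series conditions.
#' @param interactors Character vector of interactor protein ids to
#'   report.
#' @param glyco_records Glycopeptide table for dominant-type annotation
#'   (may be `NULL`).
#' @param conditions Named character vector with elements `ctrl`, `kif`,
#'   `si` giving the condition labels.
#' @param delta Relative decrease that counts as a reduction (default
#'   0.2, i.e., ratio below 0.8).
#' @return Data frame with per-protein EPO under each condition, ratios to
#'   control, `decreased_kif`/`decreased_si` flags, and `dominant_type`.
#' @export
inhibitor_comparison <- function(profiles, interactors, glyco_records = NULL,
                                 conditions = c(ctrl = "AAPL-ctrl",
                                                kif = "AAPL-Kif",
                                                si = "AAPL-SI"),
                                 delta = 0.2) {
  assert_columns(profiles, c("protein_id", "condition", "epo"), "profiles")
  if (!all(c("ctrl", "kif", "si") %in% names(conditions))) {
    abort_aaplr("conditions must name ctrl, kif, and si labels",
                "aaplr_config_error")
  }
  missing <- setdiff(unname(conditions), unique(profiles$condition))
  if (length(missing)) {
    abort_aaplr(sprintf("condition(s) absent from profiles: %s",
                        paste(missing, collapse = ", ")),
                "aaplr_config_error")
  }
  assert_scalar_number(delta, "delta", min = 0, max = 1)
  get_epo <- function(p, cc) {
    v <- profiles$epo[profiles$protein_id == p & profiles$condition == cc]
    if (length(v)) v[1] else NA_real_
  }
  rows <- lapply(interactors, function(p) {
    e_ctrl <- get_epo(p, conditions[["ctrl"]])
    e_kif <- get_epo(p, conditions[["kif"]])
    e_si <- get_epo(p, conditions[["si"]])
    r_kif <- if (!is.na(e_ctrl) && e_ctrl > 0) e_kif / e_ctrl else NA_real_
    r_si <- if (!is.na(e_ctrl) && e_ctrl > 0) e_si / e_ctrl else NA_real_
    dom <- if (!is.null(glyco_records)) {
      dominant_glyco_type(glyco_records, protein_id = p)
    } else NA_character_
    data.frame(protein_id = p, epo_ctrl = e_ctrl, epo_kif = e_kif,
               epo_si = e_si, ratio_kif = r_kif, ratio_si = r_si,
               decreased_kif = !is.na(r_kif) & r_kif < 1 - delta,
               decreased_si = !is.na(r_si) & r_si < 1 - delta,
               dominant_type = dom, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
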