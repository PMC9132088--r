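# ---- simulation parameters, experiment design, ground truth ----

# Hydroxyl-radical susceptibility defaults: sulfur-containing and aromatic
# side chains react fastest (M > W > Y > F > H ~ C), aliphatics are slow,
# everything else is near-inert but nonzero. Relative scale; M = 1.
.default_residue_weights <- c(
  M = 1.00, W = 0.80, Y = 0.60, F = 0.50, H = 0.45, C = 0.40,
  L = 0.12, I = 0.12, P = 0.12, R = 0.10, K = 0.10, V = 0.10,
  A = 0.05, D = 0.05, E = 0.05, G = 0.05, N = 0.05, Q = 0.05,
  S = 0.05, T = 0.05
)

# Average amino-acid composition of a vertebrate proteome (Swiss-Prot
# frequencies, percent); used to draw synthetic protein sequences.
.aa_frequencies <- c(
  A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, Q = 3.93, E = 6.72,
  G = 7.07, H = 2.27, I = 5.91, L = 9.65, K = 5.80, M = 2.41, F = 3.86,
  P = 4.74, S = 6.65, T = 5.35, W = 1.10, Y = 2.92, V = 6.86
)

#' Simulation parameters for synthetic AAPL experiments
#'
#' Bundles every knob of the synthetic-data generator: proteome size,
#' proximity structure, the per-residue background oxidation probability,
#' bait/proximal enrichment multipliers, residue susceptibility weights,
#' intensity and spectral-count noise models, and the digestion settings.
#'
#' The oxidation model is multiplicative: the probability that a given
#' residue is oxidized in one observation is
#' `p_background * residue_weight * enrichment(protein, condition)`,
#' where the enrichment multiplier exceeds 1 only for the bait and its
#' proximal neighbors, and only under treatment conditions. Realized
#' per-residue oxidation fractions are binomial draws over `n_molecules`
#' pseudo-molecules, so fractions are noisy but linear in the oxidation
#' probability on average.
#'
#' @param n_proteins Number of proteins in the synthetic proteome (>= 2).
#' @param n_proximal Number of truly proximal (neighbor) proteins.
#' @param p_background Per-residue background oxidation probability for a
#'   residue of susceptibility weight 1 (the most reactive residue class).
#' @param enrichment_bait,enrichment_proximal Oxidation multipliers (> 1)
#'   for the bait and for proximal proteins under the fully efficient
#'   treatment condition; `enrichment_bait >= enrichment_proximal`.
#' @param residue_weights Named numeric vector of relative susceptibilities
#'   over the 20 amino acids (>= 0). Defaults to the hydroxyl-radical
#'   footprinting reactivity order.
#' @param intensity_log_mean,intensity_log_sd Lognormal parameters for the
#'   base MS1 intensity of a peptide (arbitrary units).
#' @param replicate_log_sd Lognormal sd of the per-observation (replicate)
#'   intensity noise multiplier.
#' @param spc_per_intensity Expected spectral counts per intensity unit; a
#'   row's spectral count is Poisson with mean
#'   `spc_per_intensity * intensity`.
#' @param n_molecules Pseudo-molecule depth of the binomial draw that
#'   realizes per-residue oxidation fractions.
#' @param missed_cleavages Maximum missed tryptic cleavage sites per peptide.
#' @param peptide_min_len,peptide_max_len Detectability window: peptides
#'   outside \[min, max\] residues are dropped.
#' @param di_oxidation If `TRUE`, a residue already oxidized can acquire a
#'   second oxidation (emulated as a distinct `ox2:` peptidoform); default
#'   mono-oxidation only.
#' @param mean_protein_length Mean length of synthetic proteins (lognormal).
#' @param seed Integer seed; every generator operation is deterministic
#'   given the parameter set.
#'
#' @return An object of class `aapl_sim_params` (a validated list).
#' @examples
#' p <- sim_params(n_proteins = 20, seed = 1)
#' p$p_background
#' @export
sim_params <- function(n_proteins = 200,
                       n_proximal = 10,
                       p_background = 0.01,
                       enrichment_bait = 10,
                       enrichment_proximal = 8,
                       residue_weights = .default_residue_weights,
                       intensity_log_mean = 14,
                       intensity_log_sd = 1,
                       replicate_log_sd = 0.2,
                       spc_per_intensity = 3e-6,
                       n_molecules = 200,
                       missed_cleavages = 0,
                       peptide_min_len = 6,
                       peptide_max_len = 50,
                       di_oxidation = FALSE,
                       mean_protein_length = 350,
                       seed = 1) {
  assert_scalar_number(n_proteins, "n_proteins", min = 2, integerish = TRUE)
  assert_scalar_number(n_proximal, "n_proximal", min = 0, integerish = TRUE)
  assert_scalar_number(p_background, "p_background", min = 0, max = 1 - 1e-12)
  assert_scalar_number(enrichment_bait, "enrichment_bait", min = 1)
  assert_scalar_number(enrichment_proximal, "enrichment_proximal", min = 1)
  if (enrichment_bait < enrichment_proximal) {
    abort_aaplr("enrichment_bait must be >= enrichment_proximal",
                "aaplr_invalid_parameter")
  }
  if (!is.numeric(residue_weights) || is.null(names(residue_weights)) ||
      any(residue_weights < 0) || anyNA(residue_weights)) {
    abort_aaplr("residue_weights must be a named non-negative numeric vector",
                "aaplr_invalid_parameter")
  }
  if (p_background * max(residue_weights) * enrichment_bait > 1) {
    abort_aaplr(
      "p_background * max(residue_weights) * enrichment_bait must be <= 1",
      "aaplr_invalid_parameter")
  }
  assert_scalar_number(intensity_log_sd, "intensity_log_sd", min = 0)
  assert_scalar_number(replicate_log_sd, "replicate_log_sd", min = 0)
  assert_scalar_number(spc_per_intensity, "spc_per_intensity", min = 0)
  assert_scalar_number(n_molecules, "n_molecules", min = 1, integerish = TRUE)
  assert_scalar_number(missed_cleavages, "missed_cleavages", min = 0,
                       integerish = TRUE)
  assert_scalar_number(peptide_min_len, "peptide_min_len", min = 1,
                       integerish = TRUE)
  assert_scalar_number(peptide_max_len, "peptide_max_len",
                       min = peptide_min_len, integerish = TRUE)
  assert_scalar_number(mean_protein_length, "mean_protein_length", min = 30)
  assert_scalar_number(seed, "seed", integerish = TRUE)

  structure(list(
    n_proteins = as.integer(n_proteins),
    n_proximal = as.integer(n_proximal),
    p_background = p_background,
    enrichment_bait = enrichment_bait,
    enrichment_proximal = enrichment_proximal,
    residue_weights = residue_weights,
    intensity_log_mean = intensity_log_mean,
    intensity_log_sd = intensity_log_sd,
    replicate_log_sd = replicate_log_sd,
    spc_per_intensity = spc_per_intensity,
    n_molecules = as.integer(n_molecules),
    missed_cleavages = as.integer(missed_cleavages),
    peptide_min_len = as.integer(peptide_min_len),
    peptide_max_len = as.integer(peptide_max_len),
    di_oxidation = isTRUE(di_oxidation),
    mean_protein_length = mean_protein_length,
    seed = as.integer(seed)
  ), class = "aapl_sim_params")
}

#' Experiment design: treatment and control conditions, replicates
#'
#' AAPL experiments compare several labeling conditions (varying
#' antibody-to-probe ratios, `M1`-`M6` by default) against three controls:
#' cells only (`C1`), cells with unmodified antibody (`C2`), and cells with
#' peroxide only (`C3`). One treatment condition - the optimal one - is
#' selected for interaction scoring.
#'
#' @param treatments Ordered character vector of treatment condition ids.
#' @param controls Ordered character vector of control condition ids.
#' @param selected Condition id used for AAPL scoring; must be a treatment.
#' @param replicates Number of replicates per condition (>= 2).
#' @param condition_efficiency Optional named numeric vector in (0, 1]
#'   giving the labeling efficiency of each treatment condition relative to
#'   the fully efficient one. The effective oxidation multiplier of a
#'   bait/proximal protein under treatment `c` is
#'   `1 + (enrichment - 1) * condition_efficiency[c]`. By default the
#'   selected condition has efficiency 1 and the remaining treatments ramp
#'   over \[0.3, 0.8\], emulating sub-optimal probe ratios.
#'
#' @return An object of class `aapl_design`.
#' @examples
#' d <- experiment_design()
#' d$selected
#' @export
experiment_design <- function(treatments = paste0("M", 1:6),
                              controls = paste0("C", 1:3),
                              selected = "M5",
                              replicates = 3,
                              condition_efficiency = NULL) {
  treatments <- as.character(treatments)
  controls <- as.character(controls)
  if (!length(treatments)) {
    abort_aaplr("at least one treatment condition is required",
                "aaplr_invalid_parameter")
  }
  all_cond <- c(treatments, controls)
  if (anyDuplicated(all_cond)) {
    abort_aaplr("condition ids must be unique across treatments and controls",
                "aaplr_invalid_parameter")
  }
  if (!selected %in% treatments) {
    abort_aaplr(sprintf(
      "selected condition '%s' is not among the treatment conditions", selected),
      "aaplr_invalid_parameter")
  }
  assert_scalar_number(replicates, "replicates", min = 2, integerish = TRUE)

  if (is.null(condition_efficiency)) {
    others <- setdiff(treatments, selected)
    eff <- setNames(rep(1, length(treatments)), treatments)
    if (length(others)) {
      eff[others] <- seq(0.3, 0.8, length.out = length(others))
    }
    condition_efficiency <- eff
  } else {
    if (is.null(names(condition_efficiency)) ||
        !all(treatments %in% names(condition_efficiency))) {
      abort_aaplr("condition_efficiency must be named and cover all treatments",
                  "aaplr_invalid_parameter")
    }
    condition_efficiency <- condition_efficiency[treatments]
    if (any(condition_efficiency <= 0) || any(condition_efficiency > 1)) {
      abort_aaplr("condition_efficiency values must lie in (0, 1]",
                  "aaplr_invalid_parameter")
    }
  }

  structure(list(
    treatments = treatments,
    controls = controls,
    selected = selected,
    replicates = as.integer(replicates),
    condition_efficiency = condition_efficiency
  ), class = "aapl_design")
}

#' Ground truth for a synthetic AAPL experiment
#'
#' Assigns every protein of a synthetic proteome to a proximity class -
#' `bait`, `proximal`, or `background` - and attaches the per-protein
#' oxidation enrichment multiplier (>= 1; exactly 1 for background).
#'
#' @param proteome Data frame with a `protein_id` column (see
#'   [generate_proteome()]).
#' @param bait_id Protein id of the bait (antibody-targeted antigen).
#' @param params An [sim_params()] object supplying `n_proximal` and the
#'   enrichment multipliers.
#' @param proximal_ids Optional explicit character vector of proximal
#'   protein ids; when `NULL`, `params$n_proximal` proteins are sampled
#'   (deterministically from `params$seed`) from the non-bait proteins.
#'
#' @return Data frame of class `aapl_truth` with columns `protein_id`,
#'   `class`, `enrichment`.
#' @examples
#' pr <- generate_proteome(sim_params(n_proteins = 10, seed = 1))
#' tr <- make_ground_truth(pr, bait_id = pr$protein_id[1],
#'                         params = sim_params(n_proteins = 10, n_proximal = 3))
#' table(tr$class)
#' @export
make_ground_truth <- function(proteome, bait_id, params,
                              proximal_ids = NULL) {
  assert_columns(proteome, "protein_id", "proteome")
  ids <- proteome$protein_id
  if (!bait_id %in% ids) {
    abort_aaplr(sprintf("bait '%s' is not in the proteome", bait_id),
                "aaplr_invalid_parameter")
  }
  if (is.null(proximal_ids)) {
    pool <- setdiff(ids, bait_id)
    if (params$n_proximal > length(pool)) {
      abort_aaplr("n_proximal exceeds the number of non-bait proteins",
                  "aaplr_invalid_parameter")
    }
    proximal_ids <- withr::with_seed(params$seed,
      sample(pool, params$n_proximal))
  } else {
    proximal_ids <- as.character(proximal_ids)
    if (bait_id %in% proximal_ids || !all(proximal_ids %in% ids)) {
      abort_aaplr("proximal_ids must be non-bait proteins of the proteome",
                  "aaplr_invalid_parameter")
    }
  }
  cls <- ifelse(ids == bait_id, "bait",
                ifelse(ids %in% proximal_ids, "proximal", "background"))
  enr <- ifelse(cls == "bait", params$enrichment_bait,
                ifelse(cls == "proximal", params$enrichment_proximal, 1))
  structure(
    data.frame(protein_id = ids, class = cls, enrichment = enr,
               stringsAsFactors = FALSE),
    class = c("aapl_truth", "data.frame"),
    bait_id = bait_id
  )
}
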