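# ---- proximity-dependent oxidation simulator ----

# effective oxidation multiplier per protein x condition
condition_multipliers <- function(truth, design) {
  conds <- c(design$treatments, design$controls)
  mult <- matrix(1, nrow = nrow(truth), ncol = length(conds),
                 dimnames = list(truth$protein_id, conds))
  eff <- design$condition_efficiency
  for (cc in design$treatments) {
    mult[, cc] <- 1 + (truth$enrichment - 1) * eff[[cc]]
  }
  mult
}

#' Simulate a quantified AAPL oxidative proteomics experiment
#'
#' Emulates the measurable output of one AAPL experiment: every tryptic
#' peptide of every protein is observed in every condition and replicate as
#' an unmodified peptidoform plus, when oxidation occurred, one oxidized
#' peptidoform per oxidized residue. The per-residue oxidation probability
#' is `p_background * residue_weight * multiplier(protein, condition)`,
#' where the multiplier exceeds 1 only for the bait and proximal proteins
#' under treatment conditions (scaled by the condition's labeling
#' efficiency) and is exactly 1 in all control conditions. The realized
#' oxidation fraction of a residue is a binomial draw over
#' `params$n_molecules` pseudo-molecules; the peptide's base intensity
#' (lognormal, with per-replicate lognormal noise) is split exactly between
#' the unmodified form and the oxidized forms according to the realized
#' fractions, and each row's spectral count is Poisson with mean
#' proportional to its intensity.
#'
#' @param proteome Data frame from [generate_proteome()] (columns
#'   `protein_id`, `sequence`).
#' @param truth Ground truth from [make_ground_truth()]; must cover every
#'   protein of the proteome.
#' @param design An [experiment_design()].
#' @param params An [sim_params()].
#' @return Data frame of peptide measurements with columns `protein_id`,
#'   `peptide`, `start`, `end`, `mod` (`"none"` or `"ox:<protein
#'   position>"`), `condition`, `replicate`, `intensity`,
#'   `spectral_count`. Deterministic given `params$seed`.
#' @examples
#' p <- sim_params(n_proteins = 4, n_proximal = 1, seed = 3)
#' pr <- generate_proteome(p)
#' tr <- make_ground_truth(pr, pr$protein_id[1], p)
#' d <- experiment_design(treatments = c("M1", "M2"), selected = "M2",
#'                        controls = "C1", replicates = 2)
#' head(simulate_experiment(pr, tr, d, p))
#' @export
simulate_experiment <- function(proteome, truth, design, params) {
  if (!inherits(design, "aapl_design")) {
    abort_aaplr("design must be created with experiment_design()",
                "aaplr_invalid_parameter")
  }
  if (!inherits(params, "aapl_sim_params")) {
    abort_aaplr("params must be created with sim_params()",
                "aaplr_invalid_parameter")
  }
  if (!all(proteome$protein_id %in% truth$protein_id)) {
    abort_aaplr("ground truth does not cover every protein of the proteome",
                "aaplr_consistency_error")
  }
  truth <- truth[match(proteome$protein_id, truth$protein_id), ]

  peps <- digest_proteome(proteome, params)
  n_pep <- nrow(peps)
  mult <- condition_multipliers(truth, design)

  # residue-level expansion: one row per oxidizable residue of each peptide
  res_list <- strsplit(peps$peptide, "")
  res_per_pep <- lengths(res_list)
  res_pep_idx <- rep.int(seq_len(n_pep), res_per_pep)
  res_aa <- unlist(res_list, use.names = FALSE)
  res_w <- params$residue_weights[res_aa]
  res_w[is.na(res_w)] <- 0
  res_pos <- unlist(lapply(seq_len(n_pep), function(i) {
    peps$start[i]:peps$end[i]
  }), use.names = FALSE)
  keep <- res_w > 0
  res_pep_idx <- res_pep_idx[keep]
  res_w <- res_w[keep]
  res_pos <- res_pos[keep]
  n_res <- length(res_w)

  pep_prot_row <- match(peps$protein_id, proteome$protein_id)
  res_prot_row <- pep_prot_row[res_pep_idx]
  K <- params$n_molecules
  conds <- colnames(mult)

  withr::with_seed(params$seed, {
    b0 <- rlnorm(n_pep, params$intensity_log_mean, params$intensity_log_sd)
    blocks <- vector("list", length(conds) * design$replicates)
    bi <- 0L
    for (cc in conds) {
      p_res <- pmin(1, params$p_background * res_w * mult[res_prot_row, cc])
      for (rr in seq_len(design$replicates)) {
        bi <- bi + 1L
        b <- b0 * rlnorm(n_pep, 0, params$replicate_log_sd)
        f <- rbinom(n_res, K, p_res) / K
        if (params$di_oxidation) {
          # a second hit on an already-oxidized residue keeps the row but
          # does not change the mono/di intensity split modeled here
          f <- pmin(1, f * (1 + rbinom(n_res, K, p_res) / K))
        }
        fsum <- as.vector(rowsum(f, res_pep_idx,
                                 reorder = FALSE))          # by first appearance
        fsum_pep <- numeric(n_pep)
        fsum_pep[unique(res_pep_idx)] <- fsum
        over <- fsum_pep > 1
        if (any(over)) {                                    # cap total oxidation
          scale <- ifelse(over[res_pep_idx], 1 / fsum_pep[res_pep_idx], 1)
          f <- f * scale
          fsum_pep <- pmin(fsum_pep, 1)
        }
        unmod_int <- b * (1 - fsum_pep)
        hit <- f > 0
        ox_pep <- res_pep_idx[hit]
        ox_int <- b[ox_pep] * f[hit]
        intensity <- c(unmod_int, ox_int)
        spc <- rpois(length(intensity), params$spc_per_intensity * intensity)
        blocks[[bi]] <- data.frame(
          protein_id = c(peps$protein_id, peps$protein_id[ox_pep]),
          peptide = c(peps$peptide, peps$peptide[ox_pep]),
          start = c(peps$start, peps$start[ox_pep]),
          end = c(peps$end, peps$end[ox_pep]),
          mod = c(rep("none", n_pep),
                  paste0("ox:", res_pos[hit], recycle0 = TRUE)),
          condition = cc,
          replicate = rr,
          intensity = intensity,
          spectral_count = spc,
          stringsAsFactors = FALSE
        )
      }
    }
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Simulate a STRING-style known-interaction edge list
#'
#' Emulates the partial overlap between proximity-labeled neighbors and
#' literature-derived interaction databases: a fraction `overlap_fraction`
#' of the truly proximal proteins receive a direct bait edge (combined
#' score uniform in \[0.4, 1\]), and `n_decoy_edges` decoy edges connect
#' random pairs of background proteins. No self edges, no duplicate pairs.
#'
#' @param truth Ground truth from [make_ground_truth()].
#' @param overlap_fraction Fraction of proximal proteins with a bait edge
#'   (in \[0, 1\]); the count is `round(overlap_fraction * n_proximal)`.
#' @param n_decoy_edges Number of decoy background-background edges.
#' @param seed Integer seed.
#' @return Data frame with columns `protein_a`, `protein_b`,
#'   `combined_score` (numeric in \[0, 1\]).
#' @export
simulate_string_edges <- function(truth, overlap_fraction = 0.5,
                                  n_decoy_edges = 50, seed = 1) {
  assert_scalar_number(overlap_fraction, "overlap_fraction", min = 0, max = 1)
  assert_scalar_number(n_decoy_edges, "n_decoy_edges", min = 0,
                       integerish = TRUE)
  bait <- attr(truth, "bait_id")
  prox <- truth$protein_id[truth$class == "proximal"]
  bg <- truth$protein_id[truth$class == "background"]
  n_hit <- round(overlap_fraction * length(prox))
  withr::with_seed(seed, {
    hit <- if (n_hit > 0) sample(prox, n_hit) else character(0)
    bait_edges <- if (n_hit > 0) {
      data.frame(protein_a = bait, protein_b = hit,
                 combined_score = runif(n_hit, 0.4, 1),
                 stringsAsFactors = FALSE)
    }
    decoys <- NULL
    if (n_decoy_edges > 0 && length(bg) >= 2) {
      a <- sample(bg, 3 * n_decoy_edges, replace = TRUE)
      b <- sample(bg, 3 * n_decoy_edges, replace = TRUE)
      ok <- a != b & !duplicated(pair_key(a, b))
      a <- a[ok][seq_len(min(n_decoy_edges, sum(ok)))]
      b <- b[ok][seq_len(min(n_decoy_edges, sum(ok)))]
      decoys <- data.frame(protein_a = a, protein_b = b,
                           combined_score = runif(length(a), 0.4, 1),
                           stringsAsFactors = FALSE)
    }
  })
  out <- rbind(bait_edges, decoys)
  if (is.null(out)) {
    out <- data.frame(protein_a = character(0), protein_b = character(0),
                      combined_score = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Simulate a complete ground-truthed AAPL experiment
#'
#' Convenience wrapper chaining [generate_proteome()],
#' [make_ground_truth()], [simulate_experiment()], and
#' [simulate_string_edges()].
#'
#' @param params An [sim_params()].
#' @param design An [experiment_design()].
#' @param bait_id Bait protein id; defaults to the first generated protein.
#' @param proximal_ids Optional explicit proximal set (see
#'   [make_ground_truth()]).
#' @param overlap_fraction,n_decoy_edges Passed to
#'   [simulate_string_edges()].
#' @return List of class `aapl_sim` with elements `proteome`, `truth`,
#'   `design`, `params`, `measurements`, `edges`, `bait_id`.
#' @examples
#' sim <- simulate_aapl_experiment(sim_params(n_proteins = 6, n_proximal = 2,
#'                                            seed = 2),
#'                                 experiment_design(replicates = 2))
#' table(sim$truth$class)
#' @export
simulate_aapl_experiment <- function(params = sim_params(),
                                     design = experiment_design(),
                                     bait_id = NULL,
                                     proximal_ids = NULL,
                                     overlap_fraction = 0.5,
                                     n_decoy_edges = 50) {
  proteome <- generate_proteome(params)
  bait_id <- bait_id %||% proteome$protein_id[1]
  truth <- make_ground_truth(proteome, bait_id, params,
                             proximal_ids = proximal_ids)
  measurements <- simulate_experiment(proteome, truth, design, params)
  edges <- simulate_string_edges(truth, overlap_fraction = overlap_fraction,
                                 n_decoy_edges = n_decoy_edges,
                                 seed = params$seed)
  structure(list(proteome = proteome, truth = truth, design = design,
                 params = params, measurements = measurements,
                 edges = edges, bait_id = bait_id),
            class = "aapl_sim")
}
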