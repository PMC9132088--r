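# ---- site degree of oxidation, EPO, fold changes, tests, regions ----

is_oxidized <- function(mod) mod != "none"

mod_position <- function(mod) {
  pos <- rep(NA_integer_, length(mod))
  ox <- grepl("^ox2?:", mod)
  pos[ox] <- as.integer(sub("^ox2?:", "", mod[ox]))
  pos
}

#' Site-level degree of oxidation for one tryptic peptide
#'
#' For one peptide in one condition, the degree of oxidation of a site is
#' the ratio of the oxidized peptidoform intensity at that site to the
#' summed unmodified plus modified intensities of the peptide. Replicate
#' intensities are summed before forming the ratio.
#'
#' @param x Peptide measurement rows sharing one `(protein_id, peptide,
#'   condition)`; mixing peptides or conditions is an error.
#' @return Data frame with columns `position`, `degree` (one row per
#'   oxidized position; empty when there are no oxidized rows or the
#'   total intensity is zero).
#' @examples
#' x <- data.frame(protein_id = "P1", peptide = "SAMPLEK", start = 40, end = 46,
#'                 mod = c("none", "ox:42"), condition = "M5", replicate = 1,
#'                 intensity = c(8e6, 2e6), spectral_count = c(8, 2))
#' site_degree(x)  # degree 0.2 at position 42
#' @export
site_degree <- function(x) {
  assert_columns(x, c("protein_id", "peptide", "mod", "condition", "intensity"),
                 "site_degree input")
  if (length(unique(x$protein_id)) > 1L || length(unique(x$peptide)) > 1L ||
      length(unique(x$condition)) > 1L) {
    abort_aaplr("site_degree expects rows of a single peptide and condition",
                "aaplr_grouping_error")
  }
  total <- sum(x$intensity)
  pos <- mod_position(x$mod)
  ox <- !is.na(pos)
  if (!any(ox) || total <= 0) {
    return(data.frame(position = integer(0), degree = numeric(0)))
  }
  by_pos <- rowsum(x$intensity[ox], pos[ox])
  data.frame(position = as.integer(rownames(by_pos)),
             degree = as.vector(by_pos) / total,
             row.names = NULL)
}

#' Site degrees of oxidation for a whole measurement table
#'
#' Applies the per-peptide intensity ratio to every `(protein, peptide,
#' condition)` group (replicates summed) and aggregates to one degree per
#' `(protein, position, condition)`. When a position is covered by several
#' peptides (missed cleavage products), the per-peptide degrees are
#' combined as a mean weighted by total peptide intensity.
#'
#' @param measurements Peptide measurement table
#'   (see [read_peptide_table()]).
#' @return Data frame with columns `protein_id`, `position`, `condition`,
#'   `degree`.
#' @export
site_degrees <- function(measurements) {
  x <- measurements
  pos <- mod_position(x$mod)
  grp <- paste(x$protein_id, x$peptide, x$start, x$condition, sep = "\r")
  total <- rowsum(x$intensity, grp)            # per peptide-group totals
  ox <- !is.na(pos)
  if (!any(ox)) {
    return(data.frame(protein_id = character(0), position = integer(0),
                      condition = character(0), degree = numeric(0)))
  }
  okey <- paste(grp[ox], pos[ox], sep = "\r")
  oint <- rowsum(x$intensity[ox], okey)
  parts <- do.call(rbind, strsplit(rownames(oint), "\r", fixed = TRUE))
  gkey <- apply(parts[, 1:4, drop = FALSE], 1, paste, collapse = "\r")
  tot <- total[gkey, 1]
  keep <- tot > 0
  d <- data.frame(protein_id = parts[keep, 1],
                  condition = parts[keep, 4],
                  position = as.integer(parts[keep, 5]),
                  degree = as.vector(oint)[keep] / tot[keep],
                  weight = tot[keep],
                  stringsAsFactors = FALSE)
  # weighted mean across peptides covering the same protein position
  skey <- paste(d$protein_id, d$position, d$condition, sep = "\r")
  num <- rowsum(d$degree * d$weight, skey)
  den <- rowsum(d$weight, skey)
  parts <- do.call(rbind, strsplit(rownames(num), "\r", fixed = TRUE))
  out <- data.frame(protein_id = parts[, 1],
                    position = as.integer(parts[, 2]),
                    condition = parts[, 3],
                    degree = as.vector(num / den),
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein_id, out$condition, out$position), ]
  rownames(out) <- NULL
  out
}

#' Extent of protein oxidation (EPO) for one protein and condition
#'
#' EPO is the ratio of the summed oxidized peptide intensities to the
#' summed total (modified plus unmodified) peptide intensities of the
#' protein.
#'
#' @param x Measurement rows of a single protein in a single condition.
#' @return EPO in \[0, 1\], or `NA` when the total intensity is zero.
#' @examples
#' x <- data.frame(protein_id = "P1", peptide = c("A", "A", "B"),
#'                 start = 1, end = 7,
#'                 mod = c("none", "ox:3", "none"), condition = "M5",
#'                 replicate = 1, intensity = c(8e6, 2e6, 1e7),
#'                 spectral_count = 1)
#' protein_epo(x)  # 2e6 / 2e7 = 0.1
#' @export
protein_epo <- function(x) {
  assert_columns(x, c("protein_id", "mod", "condition", "intensity"),
                 "protein_epo input")
  if (length(unique(x$protein_id)) > 1L || length(unique(x$condition)) > 1L) {
    abort_aaplr("protein_epo expects rows of a single protein and condition",
                "aaplr_grouping_error")
  }
  total <- sum(x$intensity)
  if (total <= 0) return(NA_real_)
  sum(x$intensity[is_oxidized(x$mod)]) / total
}

# replicate-level EPO table: protein_id, condition, replicate, epo
replicate_epo <- function(measurements) {
  x <- measurements
  key <- paste(x$protein_id, x$condition, x$replicate, sep = "\r")
  tot <- rowsum(x$intensity, key)
  oxi <- rowsum(x$intensity * is_oxidized(x$mod), key)
  parts <- do.call(rbind, strsplit(rownames(tot), "\r", fixed = TRUE))
  data.frame(protein_id = parts[, 1], condition = parts[, 2],
             replicate = as.integer(parts[, 3]),
             epo = ifelse(tot[, 1] > 0, oxi[, 1] / tot[, 1], NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-protein oxidation profiles across conditions
#'
#' The protein-level summary driving everything downstream: for every
#' `(protein, condition)` it computes the EPO (replicates summed), the EPO
#' normalized to the protein's largest EPO across conditions, the EPO fold
#' change versus the mean control EPO, the number of distinct oxidized
#' sites, and the summed oxidized spectral count. When `design` is given,
#' a one-sided Welch t-test of replicate-level EPO (treatment vs pooled
#' controls) is run per protein and treatment condition, with
#' Benjamini-Hochberg correction across proteins within each condition.
#'
#' @param measurements Peptide measurement table.
#' @param design An [experiment_design()]; controls are taken from it. When
#'   `NULL`, fold changes and tests are skipped.
#' @param fc_floor Floor applied to the mean control EPO in the fold-change
#'   denominator (default `1e-4`); `fc_capped` flags proteins where the
#'   floor was hit.
#' @return Data frame with columns `protein_id`, `condition`, `epo`,
#'   `epo_norm`, `epo_fc`, `fc_capped`, `n_sites`, `ox_spectral_count`,
#'   `p_value`, `q_value`. Undefined quantities are `NA`.
#' @export
oxidation_profiles <- function(measurements, design = NULL, fc_floor = 1e-4) {
  x <- measurements
  key <- paste(x$protein_id, x$condition, sep = "\r")
  tot <- rowsum(x$intensity, key)
  ox <- is_oxidized(x$mod)
  oxi <- rowsum(x$intensity * ox, key)
  oxspc <- rowsum(x$spectral_count * ox, key)
  parts <- do.call(rbind, strsplit(rownames(tot), "\r", fixed = TRUE))
  prof <- data.frame(
    protein_id = parts[, 1], condition = parts[, 2],
    epo = ifelse(tot[, 1] > 0, oxi[, 1] / tot[, 1], NA_real_),
    n_sites = 0L,
    ox_spectral_count = as.integer(oxspc[, 1]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  sd_tab <- site_degrees(measurements)
  sd_tab <- sd_tab[sd_tab$degree > 0, ]
  if (nrow(sd_tab)) {
    cnt <- rowsum(rep(1L, nrow(sd_tab)),
                  paste(sd_tab$protein_id, sd_tab$condition, sep = "\r"))
    idx <- match(rownames(cnt), paste(prof$protein_id, prof$condition,
                                      sep = "\r"))
    prof$n_sites[idx] <- as.integer(cnt[, 1])
  }
  prof <- normalize_epo(prof)
  if (!is.null(design)) {
    prof <- epo_fold_change(prof, design$controls, fc_floor = fc_floor)
    tests <- test_epo_vs_controls(measurements, design)
    prof <- merge(prof, tests, by = c("protein_id", "condition"),
                  all.x = TRUE, sort = FALSE)
  } else {
    prof$epo_fc <- NA_real_
    prof$fc_capped <- NA
    prof$p_value <- NA_real_
    prof$q_value <- NA_real_
  }
  prof <- prof[order(prof$protein_id, prof$condition), ]
  rownames(prof) <- NULL
  prof
}

#' Normalize EPO to the per-protein maximum across conditions
#'
#' Each protein's EPO values are divided by its largest EPO over all
#' conditions, so the maximum condition gets 1. Proteins with all-zero (or
#' undefined) EPO get 0 everywhere.
#'
#' @param profiles Data frame with `protein_id`, `condition`, `epo`.
#' @return `profiles` with an `epo_norm` column added/replaced.
#' @export
normalize_epo <- function(profiles) {
  assert_columns(profiles, c("protein_id", "condition", "epo"), "profiles")
  mx <- tapply(profiles$epo, profiles$protein_id, function(v) {
    if (all(is.na(v))) 0 else max(v, na.rm = TRUE)
  })
  m <- as.vector(mx[profiles$protein_id])
  profiles$epo_norm <- ifelse(m > 0, profiles$epo / m, 0)
  profiles$epo_norm[is.na(profiles$epo)] <- NA_real_
  profiles
}

#' EPO fold change versus control conditions
#'
#' The fold change of a condition's EPO relative to the mean EPO over the
#' control conditions, with a small floor on the denominator to keep the
#' ratio finite when the controls show no oxidation at all.
#'
#' @param profiles Data frame with `protein_id`, `condition`, `epo`.
#' @param controls Character vector of control condition ids.
#' @param fc_floor Denominator floor (default `1e-4`).
#' @return `profiles` with `epo_fc` (NA when the protein has no control
#'   data) and logical `fc_capped` columns added.
#' @export
epo_fold_change <- function(profiles, controls, fc_floor = 1e-4) {
  assert_columns(profiles, c("protein_id", "condition", "epo"), "profiles")
  if (!length(intersect(controls, profiles$condition))) {
    abort_aaplr("none of the control conditions appear in the profiles",
                "aaplr_invalid_parameter")
  }
  ctl <- profiles[profiles$condition %in% controls & !is.na(profiles$epo), ]
  ctl_mean <- tapply(ctl$epo, ctl$protein_id, mean)
  m <- as.vector(ctl_mean[profiles$protein_id])
  denom <- pmax(m, fc_floor)
  profiles$epo_fc <- ifelse(is.na(m), NA_real_, profiles$epo / denom)
  profiles$fc_capped <- !is.na(m) & m < fc_floor
  profiles
}

#' Count distinct oxidized sites of a protein in a condition
#'
#' @param measurements Peptide measurement table.
#' @param protein_id,condition The protein and condition to count in.
#' @return Number of distinct protein positions with degree of oxidation
#'   greater than zero.
#' @export
count_sites <- function(measurements, protein_id, condition) {
  sd_tab <- site_degrees(
    measurements[measurements$protein_id == protein_id &
                 measurements$condition == condition, , drop = FALSE])
  sum(sd_tab$degree > 0)
}

#' Conditions-by-proteins EPO matrix and condition clustering
#'
#' Builds the matrix behind the condition heatmap (rows = conditions,
#' columns = proteins; undefined EPO as 0) and clusters the conditions by
#' correlation distance (`1 - Pearson r`) with average linkage. Leaf order
#' is made deterministic by seriating ties on condition id.
#'
#' @param profiles Output of [oxidation_profiles()].
#' @return List with `matrix` (conditions x proteins), `hclust` (or `NULL`
#'   when fewer than 3 conditions), and `order` (condition ids in leaf
#'   order).
#' @export
condition_matrix <- function(profiles) {
  assert_columns(profiles, c("protein_id", "condition", "epo"), "profiles")
  conds <- sort(unique(profiles$condition))
  prots <- sort(unique(profiles$protein_id))
  if (length(conds) < 2) {
    abort_aaplr("at least 2 conditions are required", "aaplr_invalid_parameter")
  }
  m <- matrix(0, nrow = length(conds), ncol = length(prots),
              dimnames = list(conds, prots))
  v <- ifelse(is.na(profiles$epo), 0, profiles$epo)
  m[cbind(match(profiles$condition, conds),
          match(profiles$protein_id, prots))] <- v
  if (length(conds) == 2) {
    return(list(matrix = m, hclust = NULL, order = conds))
  }
  cc <- suppressWarnings(cor(t(m)))
  cc[is.na(cc)] <- 0                         # constant rows: no information
  hc <- hclust(as.dist(1 - cc), method = "average")
  list(matrix = m, hclust = hc, order = conds[hc$order])
}

#' Test per-protein EPO of treatment conditions against pooled controls
#'
#' Replicate-level EPO values of each treatment condition are compared to
#' the pooled replicate-level control EPOs by a one-sided Welch t-test
#' (alternative: treatment greater), followed by Benjamini-Hochberg
#' correction across proteins within each treatment condition. Proteins
#' with fewer than 2 usable replicates on either side, or with zero
#' variance in both groups, get `NA`.
#'
#' @param measurements Peptide measurement table.
#' @param design An [experiment_design()].
#' @return Data frame with `protein_id`, `condition`, `p_value`, `q_value`
#'   (treatment conditions only).
#' @export
test_epo_vs_controls <- function(measurements, design) {
  rep_epo <- replicate_epo(measurements)
  rep_epo <- rep_epo[!is.na(rep_epo$epo), ]
  ctl <- rep_epo[rep_epo$condition %in% design$controls, ]
  ctl_by_prot <- split(ctl$epo, ctl$protein_id)
  out <- list()
  for (cc in design$treatments) {
    trt <- rep_epo[rep_epo$condition == cc, ]
    trt_by_prot <- split(trt$epo, trt$protein_id)
    prots <- sort(unique(c(trt$protein_id, ctl$protein_id)))
    p <- vapply(prots, function(pr) {
      a <- trt_by_prot[[pr]]
      b <- ctl_by_prot[[pr]]
      if (is.null(a) || is.null(b)) return(NA_real_)
      if (length(a) < 2 || length(b) < 2) return(NA_real_)
      if (sd(a) == 0 && sd(b) == 0) return(NA_real_)
      tryCatch(t.test(a, b, alternative = "greater")$p.value,
               error = function(e) NA_real_)
    }, numeric(1))
    out[[cc]] <- data.frame(protein_id = prots, condition = cc,
                            p_value = p,
                            q_value = p.adjust(p, method = "BH"),
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Map oxidized sites onto annotated protein regions
#'
#' Each oxidized site is assigned to every region whose interval contains
#' it (regions may overlap, so a site can be counted several times); sites
#' matching no region of their protein are reported under region
#' `"unassigned"`.
#'
#' @param sites Site table from [site_degrees()].
#' @param regions Region annotation table (see [read_region_table()]); may
#'   be empty.
#' @return Data frame with `protein_id`, `region_name`, `condition`,
#'   `n_sites`, `degree_sum`.
#' @export
map_sites_to_regions <- function(sites, regions) {
  assert_columns(sites, c("protein_id", "position", "condition", "degree"),
                 "site table")
  if (is.null(regions) || !nrow(regions)) {
    regions <- data.frame(protein_id = character(0), region_name = character(0),
                          start = integer(0), end = integer(0))
  }
  assert_columns(regions, c("protein_id", "region_name", "start", "end"),
                 "region table")
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    hit <- regions[regions$protein_id == s$protein_id &
                   regions$start <= s$position &
                   regions$end >= s$position, , drop = FALSE]
    rn <- if (nrow(hit)) hit$region_name else "unassigned"
    rows[[i]] <- data.frame(protein_id = s$protein_id, region_name = rn,
                            condition = s$condition, degree = s$degree,
                            stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rows)
  if (is.null(long)) {
    return(data.frame(protein_id = character(0), region_name = character(0),
                      condition = character(0), n_sites = integer(0),
                      degree_sum = numeric(0)))
  }
  key <- paste(long$protein_id, long$region_name, long$condition, sep = "\r")
  n <- rowsum(rep(1L, nrow(long)), key)
  dsum <- rowsum(long$degree, key)
  parts <- do.call(rbind, strsplit(rownames(n), "\r", fixed = TRUE))
  data.frame(protein_id = parts[, 1], region_name = parts[, 2],
             condition = parts[, 3], n_sites = as.integer(n[, 1]),
             degree_sum = as.vector(dsum), stringsAsFactors = FALSE,
             row.names = NULL)
}
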