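# site degrees, EPO, normalization, fold change, clustering, tests, regions

test_that("site degree is the oxidized/total intensity ratio", {
  x <- tiny_measurements()
  d <- site_degree(x[x$peptide == "SAMPLEK", ])
  expect_equal(d$position, 42L)
  expect_equal(d$degree, 2e6 / 1e7)  # hand ratio: 2e6 / (8e6 + 2e6)

  # no oxidized rows -> empty
  expect_equal(nrow(site_degree(x[3, ])), 0)

  # fully oxidized peptide: degree 1
  x1 <- x[2, ]; x1$intensity <- 5e6
  expect_equal(site_degree(x1)$degree, 1)

  # mixed peptides are a grouping error
  expect_error(site_degree(x), class = "aaplr_grouping_error")
})

test_that("protein EPO matches hand summation and its boundaries", {
  x <- tiny_measurements()
  expect_equal(protein_epo(x), 2e6 / 2e7)  # 0.10 by hand
  xu <- x[x$mod == "none", ]
  expect_equal(protein_epo(xu), 0)
  xo <- x[x$mod != "none", ]
  expect_equal(protein_epo(xo), 1)
  xz <- x; xz$intensity <- 0
  expect_true(is.na(protein_epo(xz)))
  expect_error(protein_epo(rbind(x, within(x, protein_id <- "P2"))),
               class = "aaplr_grouping_error")
})

test_that("EPO and site degrees agree with brute-force oracles", {
  withr::local_seed(101)
  for (i in 1:50) {
    x <- random_peptide_table(max_pep = 10)
    expect_equal(protein_epo(x), oracle_epo(x), tolerance = 1e-12)
    prof <- oxidation_profiles(x)
    expect_equal(prof$epo, oracle_epo(x), tolerance = 1e-12)
    expect_true(all(prof$epo >= 0 & prof$epo <= 1, na.rm = TRUE))
    # per-peptide degrees against the oracle
    for (pep in unique(x$peptide)) {
      rows <- x[x$peptide == pep, , drop = FALSE]
      got <- site_degree(rows)
      want <- oracle_site_degree(rows)
      expect_equal(got$degree, unname(want), tolerance = 1e-12)
      expect_true(all(got$degree >= 0 & got$degree <= 1))
    }
  }
})

test_that("EPO lies between the per-peptide oxidized fractions", {
  withr::local_seed(202)
  for (i in 1:20) {
    x <- random_peptide_table(max_pep = 8)
    fracs <- vapply(unique(x$peptide), function(pep) {
      r <- x[x$peptide == pep, ]
      sum(r$intensity[r$mod != "none"]) / sum(r$intensity)
    }, numeric(1))
    e <- protein_epo(x)
    expect_gte(e, min(fracs) - 1e-12)
    expect_lte(e, max(fracs) + 1e-12)
  }
})

test_that("normalization puts the max condition at 1", {
  prof <- data.frame(protein_id = "P1", condition = c("M5", "C1"),
                     epo = c(0.2, 0.05))
  n <- normalize_epo(prof)
  expect_equal(n$epo_norm, c(1, 0.25))
  # single condition -> 1
  expect_equal(normalize_epo(prof[1, ])$epo_norm, 1)
  # all-zero protein -> all zeros
  prof$epo <- 0
  expect_equal(normalize_epo(prof)$epo_norm, c(0, 0))
})

test_that("EPO fold change divides by mean control EPO with a floor", {
  prof <- data.frame(protein_id = "P1",
                     condition = c("M5", "C1", "C2"),
                     epo = c(0.15, 0.04, 0.06))
  f <- epo_fold_change(prof, controls = c("C1", "C2"))
  expect_equal(f$epo_fc[1], 0.15 / 0.05)  # 3.0 by hand
  expect_false(any(f$fc_capped))
  # treatment equal to control mean -> 1
  prof$epo[1] <- 0.05
  expect_equal(epo_fold_change(prof, c("C1", "C2"))$epo_fc[1], 1)
  # all-zero controls hit the 1e-4 floor and are flagged
  prof$epo <- c(0.1, 0, 0)
  fz <- epo_fold_change(prof, c("C1", "C2"))
  expect_equal(fz$epo_fc[1], 1000)
  expect_true(all(fz$fc_capped))
  expect_error(epo_fold_change(prof, "C9"), class = "aaplr_invalid_parameter")
})

test_that("site counts are distinct positions with positive degree", {
  x <- tiny_measurements()
  # same position from two peptidoform rows counts once
  x2 <- rbind(x, within(x[2, ], intensity <- 1e6))
  expect_equal(count_sites(x2, "P1", "M5"), 1)
  x3 <- rbind(x, within(x[2, ], mod <- "ox:44"),
              within(x[3, ], mod <- "ox:60"))
  expect_equal(count_sites(x3, "P1", "M5"), 3)
  expect_equal(count_sites(x[x$mod == "none", ], "P1", "M5"), 0)
})

test_that("condition clustering uses correlation distance deterministically", {
  prof <- expand.grid(protein_id = paste0("P", 1:6),
                      condition = c("A", "B", "C", "D"),
                      stringsAsFactors = FALSE)
  base <- c(1, 2, 3, 4, 5, 6) / 10
  prof$epo <- NA_real_
  prof$epo[prof$condition == "A"] <- base
  prof$epo[prof$condition == "B"] <- base * 1.1        # perfectly correlated
  prof$epo[prof$condition == "C"] <- rev(base)         # anti-correlated
  prof$epo[prof$condition == "D"] <- c(.2, .1, .4, .3, .6, .5)
  cm <- condition_matrix(prof)
  corm <- cor(t(cm$matrix))
  expect_equal(corm["A", "B"], 1)
  expect_equal(1 - corm["A", "C"], 2)                  # maximal distance
  # identical-profile conditions must be adjacent leaves
  ord <- cm$order
  expect_equal(abs(which(ord == "A") - which(ord == "B")), 1)
  # average-linkage heights match a hand agglomeration on the 4x4 matrix
  dm <- 1 - corm
  h <- cm$hclust
  expect_equal(h$height[1], dm["A", "B"], tolerance = 1e-12)
  # second merge: D joins {A,B} at mean(d(D,A), d(D,B))
  expect_equal(h$height[2], mean(c(dm["D", "A"], dm["D", "B"])),
               tolerance = 1e-12)
  expect_equal(h$height[3],
               mean(c(dm["C", "A"], dm["C", "B"], dm["C", "D"])),
               tolerance = 1e-12)
})

test_that("treatment-vs-control EPO test detects shifts and handles n=1", {
  # build replicate-structured measurements directly
  mk <- function(cond, rep, epo_frac) {
    data.frame(protein_id = "P1", peptide = "AAAAAA", start = 1L, end = 6L,
               mod = c("none", "ox:3"), condition = cond, replicate = rep,
               intensity = c(1e7 * (1 - epo_frac), 1e7 * epo_frac),
               spectral_count = 5L, stringsAsFactors = FALSE)
  }
  design <- experiment_design(treatments = "M1", selected = "M1",
                              controls = c("C1", "C2"), replicates = 3)
  shifted <- do.call(rbind, c(
    lapply(1:3, function(r) mk("M1", r, 0.5 + 0.01 * r)),
    lapply(1:3, function(r) mk("C1", r, 0.05 + 0.01 * r)),
    lapply(1:3, function(r) mk("C2", r, 0.05 + 0.005 * r))))
  tt <- test_epo_vs_controls(shifted, design)
  expect_lt(tt$p_value, 0.001)
  # single treatment replicate -> sentinel
  one <- do.call(rbind, c(list(mk("M1", 1, 0.5)),
                          lapply(1:3, function(r) mk("C1", r, 0.05 * r))))
  expect_true(is.na(test_epo_vs_controls(one, design)$p_value))
})

test_that("sites map to all overlapping regions, else unassigned", {
  sites <- data.frame(protein_id = "P1", position = c(100L, 30L),
                      condition = "M5", degree = c(0.2, 0.1))
  regions <- data.frame(protein_id = "P1",
                        region_name = c("ECD", "repeat1"),
                        start = c(50L, 90L), end = c(150L, 120L))
  m <- map_sites_to_regions(sites, regions)
  # site 100 is inside both overlapping regions; site 30 in none
  expect_setequal(m$region_name, c("ECD", "repeat1", "unassigned"))
  expect_equal(m$n_sites[m$region_name == "ECD"], 1L)
  expect_equal(m$degree_sum[m$region_name == "unassigned"], 0.1)
  # no annotations at all -> everything unassigned
  m0 <- map_sites_to_regions(sites, NULL)
  expect_true(all(m0$region_name == "unassigned"))
  expect_equal(sum(m0$n_sites), 2L)
})
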