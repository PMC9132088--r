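# synthetic-data generator: proteome, digestion, oxidation model, edges

test_that("generate_proteome honors the count contract and determinism", {
  p <- sim_params(n_proteins = 5, seed = 1)
  pr <- generate_proteome(p)
  expect_equal(nrow(pr), 5)
  expect_equal(anyDuplicated(pr$protein_id), 0)
  expect_true(all(nchar(pr$sequence) >= 30))
  expect_true(all(strsplit(paste(pr$sequence, collapse = ""), "")[[1]] %in%
                  LETTERS))
  expect_identical(pr, generate_proteome(p))
  pr2 <- generate_proteome(sim_params(n_proteins = 5, seed = 2))
  expect_false(identical(pr$sequence, pr2$sequence))
  expect_error(sim_params(n_proteins = 1), class = "aaplr_invalid_parameter")
})

test_that("tryptic digestion follows the K/R-not-before-P rule", {
  # hand enumeration: cuts after K4 and R8 -> AAAK, AAAR, CCCCCC
  d <- digest_protein("AAAKAAARCCCCCC", min_len = 1)
  expect_equal(d$peptide, c("AAAK", "AAAR", "CCCCCC"))
  expect_equal(d$start, c(1L, 5L, 9L))
  expect_equal(d$end, c(4L, 8L, 14L))
  # default detectability window keeps only the length-6 fragment
  expect_equal(digest_protein("AAAKAAARCCCCCC")$peptide, "CCCCCC")
  # K followed by P is not a cleavage site
  dp <- digest_protein("AAAKPAAAKAAA", min_len = 1)
  expect_equal(dp$peptide, c("AAAKPAAAK", "AAA"))
  # one missed cleavage adds the spanning products (hand enumeration)
  dm <- digest_protein("AAAKAAARCCCCCC", missed_cleavages = 1, min_len = 1)
  expect_setequal(dm$peptide,
                  c("AAAK", "AAAR", "CCCCCC", "AAAKAAAR", "AAARCCCCCC"))
  # positions are 1-based inclusive and consistent with the sequence
  expect_true(all(substring("AAAKAAARCCCCCC", dm$start, dm$end) ==
                  dm$peptide))
})

test_that("oxidation is proximity-dependent and conditions behave", {
  sim <- small_sim()
  m <- sim$measurements
  truth <- sim$truth
  expect_true(all(m$intensity >= 0))
  expect_true(all(m$spectral_count >= 0))

  # realized oxidized intensity fraction per protein class and condition
  ox_frac <- function(ids, cond) {
    x <- m[m$protein_id %in% ids & m$condition == cond, ]
    sum(x$intensity[x$mod != "none"]) / sum(x$intensity)
  }
  bait <- truth$protein_id[truth$class == "bait"]
  bg <- truth$protein_id[truth$class == "background"]
  # treatment: bait enriched over background by about the multiplier
  ratio <- ox_frac(bait, "M3") / ox_frac(bg, "M3")
  expect_gt(ratio, sim$params$enrichment_bait * 0.5)
  # controls: bait indistinguishable from background (multiplier 1)
  expect_lt(abs(ox_frac(bait, "C1") / ox_frac(bg, "C1") - 1), 0.5)

  # degenerate probability: no oxidation anywhere
  p0 <- sim_params(n_proteins = 5, n_proximal = 1, p_background = 0, seed = 3)
  m0 <- simulate_experiment(generate_proteome(p0),
                            make_ground_truth(generate_proteome(p0),
                                              "SYN0001", p0),
                            sim$design, p0)
  expect_equal(sum(m0$mod != "none"), 0)

  # determinism: identical params + seed give identical tables
  m2 <- simulate_experiment(sim$proteome, truth, sim$design, sim$params)
  expect_identical(m, m2)
})

test_that("expected oxidation increases with the enrichment multiplier", {
  design <- experiment_design(treatments = "M1", selected = "M1",
                              controls = "C1", replicates = 2)
  fracs <- vapply(c(2, 5, 10), function(enr) {
    p <- sim_params(n_proteins = 6, n_proximal = 0, enrichment_bait = enr,
                    enrichment_proximal = 1, p_background = 0.005, seed = 42)
    pr <- generate_proteome(p)
    tr <- make_ground_truth(pr, "SYN0001", p)
    m <- simulate_experiment(pr, tr, design, p)
    x <- m[m$protein_id == "SYN0001" & m$condition == "M1", ]
    sum(x$intensity[x$mod != "none"]) / sum(x$intensity)
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
})

test_that("string edge simulation respects overlap and uniqueness", {
  p <- sim_params(n_proteins = 50, n_proximal = 10, seed = 5)
  pr <- generate_proteome(p)
  tr <- make_ground_truth(pr, "SYN0001", p)
  prox <- tr$protein_id[tr$class == "proximal"]

  full <- simulate_string_edges(tr, overlap_fraction = 1, n_decoy_edges = 0,
                                seed = 1)
  expect_setequal(full$protein_b, prox)
  expect_true(all(full$protein_a == "SYN0001"))

  none <- simulate_string_edges(tr, overlap_fraction = 0, n_decoy_edges = 20,
                                seed = 1)
  expect_false(any(none$protein_a %in% c("SYN0001", prox) |
                   none$protein_b %in% c("SYN0001", prox)))

  half <- simulate_string_edges(tr, overlap_fraction = 0.5, n_decoy_edges = 0,
                                seed = 7)
  expect_equal(nrow(half), 5)  # exactly round(0.5 * 10) bait edges

  e <- simulate_string_edges(tr, overlap_fraction = 0.5, n_decoy_edges = 30,
                             seed = 2)
  expect_true(all(e$protein_a != e$protein_b))
  key <- paste(pmin(e$protein_a, e$protein_b), pmax(e$protein_a, e$protein_b))
  expect_equal(anyDuplicated(key), 0)
  expect_true(all(e$combined_score >= 0.4 & e$combined_score <= 1))
  expect_identical(e, simulate_string_edges(tr, 0.5, 30, seed = 2))
})
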