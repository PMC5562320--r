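# A fixed mini world used across the screening tests:
# drugs 1, 2; compounds 10..13; disease chemicals 20, 21; gene proteins P1, P2.
h_screen_world <- function() {
  chem <- rbind(
    h_chem_row(1, 10, 300),   # drug 1 -- compound 10
    h_chem_row(1, 11, 700),   # drug 1 -- compound 11
    h_chem_row(2, 11, 500),   # drug 2 -- compound 11
    h_chem_row(2, 1, 900),    # drug-drug link
    h_chem_row(10, 20, 300),  # compound 10 -- disease chemical
    h_chem_row(10, 21, 700),
    h_chem_row(11, 20, 800),
    h_chem_row(12, 20, 400)   # compound 12 interacts with no drug
  )
  prot <- data.frame(
    protein = c("9606.P1", "9606.P2", "9606.P9"),
    chemical = c("CID10", "CID12", "CID11"),
    experimental = 0, prediction = 0, database = 0, textmining = 0,
    combined_score = c(500, 640, 420)
  )
  w <- h_mini_world(chem, prot)
  w$inputs <- screen_inputs(c(1L, 2L), c(20L, 21L),
                            list(GA = "P1", GB = c("P2", "P3")))
  w
}

test_that("preliminary screen returns drug interactors minus the drugs", {
  w <- h_screen_world()
  # drug 1 neighbors {10, 11, 2}, drug 2 neighbors {11, 1} -> {10, 11}
  expect_identical(preliminary_screen(w$index, c(1L, 2L)), c(10L, 11L))
  expect_error(preliminary_screen(w$index, integer(0)), "empty drug")
  # no interactors at all
  lone <- h_mini_world(h_chem_row(50, 51, 10))
  expect_identical(preliminary_screen(lone$index, 99L), integer(0))
})

test_that("preliminary screen matches a brute-force scan on a random fixture", {
  w <- h_random_tables(seed = 31, n_compounds = 50, n_chem_links = 150)
  tables <- h_tables_from_paths(w)
  index <- build_index(tables)
  chem <- h_parse_raw_chem(w$chem_raw)
  drugs <- w$ids[1:5]
  expect_identical(preliminary_screen(index, drugs), bf_preliminary(chem, drugs))
})

test_that("rating score is the mean combined score, zero without links", {
  chem <- rbind(h_chem_row(5, 20, 300), h_chem_row(5, 21, 700),
                h_chem_row(5, 22, 800), h_chem_row(5, 30, 999))
  w <- h_mini_world(chem)
  expect_equal(rating_score(5, c(20L, 21L, 22L), w$index, "chemicals"), 600)
  expect_equal(rating_score(5, 21L, w$index, "chemicals"), 700)
  expect_equal(rating_score(5, c(40L, 41L), w$index, "chemicals"), 0)
  expect_equal(rating_score(77, c(20L, 21L), w$index, "chemicals"), 0)
})

test_that("association test requires both channels positive and records scores", {
  w <- h_screen_world()
  assoc <- association_test(c(10L, 11L), w$inputs, w$index)
  # compound 11 hits disease chemical 20 but no disease-gene protein
  expect_identical(assoc$compound, 10L)
  expect_equal(assoc$rs_chemicals, 500)  # mean(300, 700)
  expect_equal(assoc$rs_genes, 500)      # single P1 link
  expect_true(all(is.na(assoc$pvalue_chemicals)))
})

test_that("permutation p-value follows the strict-exceedance count", {
  # compound linked to every universe member with an identical score:
  # no random set can exceed the observed mean
  ids <- 200:209
  chem <- do.call(rbind, lapply(ids, function(b) h_chem_row(99, b, 500)))
  w <- h_mini_world(chem)
  cfg <- permutation_config(universe = ids, n_permutations = 200, seed = 4)
  expect_equal(permute_pvalue(99, 500, 3, cfg, w$index, "chemicals"), 0)
  # an observed score above every table score is never exceeded
  expect_equal(permute_pvalue(99, 1000, 3, cfg, w$index, "chemicals"), 0)
  # an observed score of 0 for a fully connected compound is always exceeded
  expect_equal(permute_pvalue(99, 0, 3, cfg, w$index, "chemicals"), 1)
  expect_error(permute_pvalue(99, 500, 50, cfg, w$index, "chemicals"),
               "exceeds universe size")
})

test_that("permutation p-values are seed-reproducible and seed-sensitive", {
  w <- h_random_tables(seed = 17, n_compounds = 30, n_chem_links = 100)
  index <- build_index(h_tables_from_paths(w))
  c <- w$ids[1]
  obs <- rating_score(c, w$ids[10:20], index, "chemicals")
  cfg <- permutation_config(index$chemical_universe, 300, seed = 8)
  p1 <- permute_pvalue(c, obs, 11, cfg, index, "chemicals")
  p2 <- permute_pvalue(c, obs, 11, cfg, index, "chemicals")
  expect_identical(p1, p2)
  expect_true(p1 >= 0 && p1 <= 1)
  expect_equal(p1 * 300, round(p1 * 300))  # multiple of 1/B
})

test_that("Monte-Carlo p-values converge to the exhaustive enumeration", {
  w <- h_random_tables(seed = 23, n_compounds = 12, n_chem_links = 40)
  index <- build_index(h_tables_from_paths(w))
  universe <- index$chemical_universe
  c <- universe[1]
  obs <- rating_score(c, universe[3:5], index, "chemicals")
  exact <- permute_pvalue(c, obs, 3,
                          permutation_config(universe, exhaustive = TRUE),
                          index, "chemicals")
  ps <- vapply(1:20, function(s) {
    permute_pvalue(c, obs, 3, permutation_config(universe, 500, seed = s),
                   index, "chemicals")
  }, numeric(1))
  se <- sqrt(exact * (1 - exact) / (20 * 500))
  expect_lt(abs(mean(ps) - exact), 3 * se + 1e-12)
})

test_that("null p-values are uniform-ish: mean near one half", {
  # compound linked to the whole universe with i.i.d. scores; the observed
  # reference set is an arbitrary fixed subset, so its rating score is an
  # exchangeable draw from the permutation null
  ids <- 300:329
  ps <- vapply(1:150, function(s) {
    set.seed(s)
    chem <- do.call(rbind, lapply(ids, function(b)
      h_chem_row(99, b, sample(1:1000, 1))))
    w <- h_mini_world(chem)
    obs <- rating_score(99, ids[1:8], w$index, "chemicals")
    cfg <- permutation_config(ids, 100, seed = s + 1000)
    permute_pvalue(99, obs, 8, cfg, w$index, "chemicals")
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 0.05)
})

test_that("thresholds are the per-channel drug maxima, applied inclusively", {
  one <- data.frame(compound = 1L, rs_chemicals = 10, rs_genes = 10,
                    pvalue_chemicals = 0.1, pvalue_genes = 0.2)
  expect_equal(select_thresholds(one), c(chemicals = 0.1, genes = 0.2))
  zeros <- data.frame(compound = 1:2, rs_chemicals = 1, rs_genes = 1,
                      pvalue_chemicals = 0, pvalue_genes = 0)
  expect_equal(select_thresholds(zeros), c(chemicals = 0, genes = 0))
  expect_error(select_thresholds(zeros[0, ]), "no drug assessments")
  expect_error(select_thresholds(data.frame(compound = 1, rs_chemicals = 1,
                                            rs_genes = 1, pvalue_chemicals = NA_real_,
                                            pvalue_genes = 0.1)), "unset")

  a <- data.frame(compound = 1:3, rs_chemicals = 1, rs_genes = 1,
                  pvalue_chemicals = c(0.469, 0.470, 0.100),
                  pvalue_genes = c(0.292, 0.100, 0.293))
  kept <- apply_thresholds(a, c(0.469, 0.292))
  expect_identical(kept$compound, 1L)  # boundary inclusive, others out
})

test_that("threshold filter matches a brute-force double filter", {
  set.seed(12)
  a <- data.frame(compound = 1:200, rs_chemicals = 1, rs_genes = 1,
                  pvalue_chemicals = round(runif(200), 3),
                  pvalue_genes = round(runif(200), 3))
  thr <- c(0.42, 0.25)
  want <- a[a$pvalue_chemicals <= 0.42 & a$pvalue_genes <= 0.25, ]
  rownames(want) <- NULL
  expect_identical(apply_thresholds(a, thr), want)
})

test_that("screening stages are nested", {
  w <- h_random_tables(seed = 41, n_compounds = 40, n_chem_links = 200,
                       n_prot_links = 120)
  index <- build_index(h_tables_from_paths(w))
  inputs <- screen_inputs(w$ids[1:4], w$ids[5:14],
                          setNames(as.list(w$proteins[1:6]), paste0("G", 1:6)))
  prelim <- preliminary_screen(index, inputs$drugs)
  assoc <- association_test(prelim, inputs, index)
  expect_true(all(assoc$compound %in% prelim))
  assoc <- assess_pvalues(assoc, inputs, index, n_permutations = 100, seed = 2)
  passed <- apply_thresholds(assoc, c(0.5, 0.5))
  expect_true(all(passed$compound %in% assoc$compound))
})
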