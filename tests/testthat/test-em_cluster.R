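test_that("k = 1 recovers the closed-form Gaussian MLE", {
  g <- generate_gmm_data(n = 80, dims = 4, k = 1, separation = 1, seed = 2)
  fit <- gmm_fit(g$data, k = 1, seed = 5)
  expect_equal(fit$weights, 1)
  expect_equal(as.numeric(fit$means), colMeans(g$data), tolerance = 1e-10)
  mle_var <- apply(g$data, 2, function(v) mean((v - mean(v))^2))
  expect_equal(as.numeric(fit$variances), pmax(mle_var, fit$var_floor),
               tolerance = 1e-8)
})

test_that("log-likelihood traces never decrease", {
  for (s in 1:4) {
    g <- generate_gmm_data(n = 120, dims = 6, k = 3, separation = 3, seed = s)
    for (k in 1:4) {
      fit <- gmm_fit(g$data, k, seed = s)
      expect_true(all(diff(fit$loglik_trace) >= -1e-8),
                  info = paste("seed", s, "k", k))
    }
  }
})

test_that("responsibilities and weights are proper distributions", {
  g <- generate_gmm_data(n = 90, dims = 5, k = 2, separation = 4, seed = 9)
  fit <- gmm_fit(g$data, k = 3, seed = 9)
  expect_equal(rowSums(fit$responsibilities), rep(1, 90), tolerance = 1e-9)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_identical(unname(fit$labels),
                   max.col(fit$responsibilities, ties.method = "first"))
})

test_that("fits are bit-reproducible under a fixed seed", {
  g <- generate_gmm_data(n = 100, dims = 5, k = 2, separation = 4, seed = 3)
  f1 <- gmm_fit(g$data, 2, seed = 11)
  f2 <- gmm_fit(g$data, 2, seed = 11)
  expect_identical(f1$means, f2$means)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
})

test_that("densities agree with a naive per-point oracle", {
  g <- generate_gmm_data(n = 25, dims = 3, k = 2, separation = 4, seed = 6)
  fit <- gmm_fit(g$data, 2, seed = 6)
  # independent likelihood: plain products of dnorm, no log-space tricks
  naive_ll <- sum(log(vapply(seq_len(nrow(g$data)), function(i) {
    sum(vapply(1:2, function(j) {
      fit$weights[j] * prod(stats::dnorm(g$data[i, ], fit$means[j, ],
                                         sqrt(fit$variances[j, ])))
    }, numeric(1)))
  }, numeric(1))))
  expect_equal(fit$loglik, naive_ll, tolerance = 1e-8)
})

test_that("well-separated planted components are recovered", {
  g <- generate_gmm_data(n = 300, dims = 15, k = 2, separation = 5, seed = 14)
  fit <- gmm_fit(g$data, 2, seed = 14)
  # match fitted to planted components by nearest mean
  d1 <- sum((fit$means[1, ] - g$means[1, ])^2)
  d2 <- sum((fit$means[2, ] - g$means[1, ])^2)
  ord <- if (d1 < d2) 1:2 else 2:1
  for (j in 1:2) {
    expect_lt(sqrt(mean((fit$means[ord[j], ] - g$means[j, ])^2)), 0.2)
  }
  expect_gte(mclust::adjustedRandIndex(fit$labels, g$labels), 0.95)
})

test_that("degenerate identical data yields a floored single component", {
  x <- matrix(5, nrow = 20, ncol = 3)
  fit <- gmm_fit(x, 1, seed = 1)
  expect_equal(as.numeric(fit$means), rep(5, 3))
  expect_true(all(fit$variances > 0))
  expect_error(gmm_fit(x, 25, seed = 1), "exceeds the number of rows")
  expect_error(gmm_fit(x, 0, seed = 1), "k must be")
})

test_that("cross-validated selection separates one from two components", {
  tight <- generate_gmm_data(n = 200, dims = 5, k = 1, separation = 1, seed = 8)
  expect_equal(select_k(tight$data, folds = 10, seed = 8, k_max = 4), 1L)
  two <- generate_gmm_data(n = 200, dims = 5, k = 2, separation = 5, seed = 8)
  expect_equal(select_k(two$data, folds = 10, seed = 8, k_max = 4), 2L)
  expect_error(select_k(matrix(rnorm(25), 5), folds = 10), "fewer rows")
})

test_that("co-cluster selection follows the drug component", {
  labels <- c(a = 3L, b = 3L, c = 1L, d = 0L + 2L, D1 = 3L, D2 = 3L)
  names(labels) <- c("7", "8", "9", "10", "1", "2")
  got <- cocluster_select(labels, drugs = c(1L, 2L), policy = "all")
  expect_identical(got, c(7L, 8L))
  # split drugs: error under "all", majority under "plurality"
  labels["2"] <- 1L
  expect_error(cocluster_select(labels, c(1L, 2L), policy = "all"),
               class = "cocluster_violation")
  err <- tryCatch(cocluster_select(labels, c(1L, 2L), policy = "all"),
                  cocluster_violation = identity)
  expect_length(err$partition, 2L)
  split <- c(rep(1L, 6), rep(2L, 4), 1L, 1L, 2L)
  names(split) <- c(101:110, 7, 8, 9)
  expect_identical(cocluster_select(split, 101:110, "plurality"), c(7L, 8L))
  expect_error(cocluster_select(unname(split), 101:110), "named")
})

test_that("refinement never grows the candidate set and respects rounds", {
  w <- h_random_tables(seed = 55, n_compounds = 40, n_chem_links = 250,
                       n_prot_links = 150)
  index <- build_index(h_tables_from_paths(w))
  inputs <- screen_inputs(w$ids[1:5], w$ids[6:15],
                          setNames(as.list(w$proteins[1:4]), paste0("G", 1:4)))
  cands <- preliminary_screen(index, inputs$drugs)
  # rounds = 0: input returned unchanged
  r0 <- iterative_refine(cands, inputs, index, rounds = 0, seed = 1)
  expect_identical(r0$candidates, cands)
  expect_equal(nrow(r0$audit), 0L)
  r3 <- iterative_refine(cands, inputs, index, rounds = 3, folds = 5, seed = 1)
  expect_true(all(r3$audit$n_survivors <= r3$audit$n_candidates))
  expect_true(all(diff(r3$audit$n_candidates) <= 0))
  expect_true(all(r3$candidates %in% cands))
})

test_that("a co-cluster fixpoint stops the refinement early", {
  # candidates drawn identical to the drugs' profile: everything co-clusters
  chem <- rbind(h_chem_row(1, 2, 900), h_chem_row(1, 30, 800),
                h_chem_row(2, 31, 800), h_chem_row(30, 20, 600),
                h_chem_row(31, 20, 600), h_chem_row(1, 20, 600),
                h_chem_row(2, 20, 600))
  prot <- data.frame(
    protein = "9606.P1", chemical = c("CID30", "CID31", "CID1", "CID2"),
    experimental = 0, prediction = 0, database = 0, textmining = 0,
    combined_score = 700
  )
  w <- h_mini_world(chem, prot)
  inputs <- screen_inputs(c(1L, 2L), 20L, list(G = "P1"))
  res <- iterative_refine(c(30L, 31L), inputs, index = w$index,
                          rounds = 5, folds = 2, k_max = 2, seed = 3)
  expect_identical(res$candidates, c(30L, 31L))
  expect_lt(nrow(res$audit), 5L)
})

test_that("gmm model methods are coherent", {
  g <- generate_gmm_data(n = 60, dims = 4, k = 2, separation = 5, seed = 21)
  fit <- gmm_fit(g$data, 2, seed = 21)
  expect_output(print(fit), "Gaussian mixture")
  expect_output(print(summary(fit)), "cluster sizes")
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), fit$loglik)
  expect_equal(attr(ll, "df"), (2 - 1) + 2 * 2 * 4)
  expect_identical(predict(fit), unname(fit$labels))
  resp <- predict(fit, g$data, type = "responsibility")
  expect_equal(rowSums(resp), rep(1, 60), tolerance = 1e-9)
  sim <- simulate(fit, nsim = 500, seed = 2)
  expect_equal(dim(sim), c(500L, 4L))
  # simulated data should be classified mostly into its generating component
  agree <- mean(predict(fit, sim) == attr(sim, "component"))
  expect_gt(agree, 0.95)
})
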