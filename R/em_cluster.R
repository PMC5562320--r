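# Diagonal-covariance Gaussian mixture fitted by expectation-maximization,
# with the component count chosen by cross-validated held-out likelihood.
# Candidates surviving the permutation test are co-clustered with the
# approved drugs in the 15-dimensional feature space; candidates sharing
# the drugs' component are retained, iteratively.

# n x k matrix of log component densities under a diagonal Gaussian model.
.log_dens <- function(x, means, variances) {
  n <- nrow(x)
  k <- nrow(means)
  d <- ncol(x)
  ld <- matrix(0, n, k)
  for (j in seq_len(k)) {
    v <- variances[j, ]
    xc <- sweep(x, 2L, means[j, ], `-`)
    ld[, j] <- -0.5 * (d * log(2 * pi) + sum(log(v)) +
                         rowSums(sweep(xc^2, 2L, v, `/`)))
  }
  ld
}

.logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Per-dimension variance floor: a small fraction of the data variance,
# falling back to the mean positive variance for constant dimensions.
.variance_floor <- function(x, frac) {
  n <- nrow(x)
  gv <- apply(x, 2L, stats::var) * (n - 1) / max(n, 1)
  base <- if (any(gv > 0)) mean(gv[gv > 0]) else 1
  pmax(frac * gv, frac * base * 1e-3, .Machine$double.xmin)
}

# Farthest-point seeding followed by a few Lloyd iterations; returns the
# k cluster centers. Assumes the RNG state is already set by the caller.
.kmeans_init <- function(x, k, iter = 10L) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (k > 1L) {
    mind <- rowSums(sweep(x, 2L, centers[1L, ], `-`)^2)
    for (j in 2L:k) {
      idx <- which.max(mind)
      centers[j, ] <- x[idx, ]
      dj <- rowSums(sweep(x, 2L, centers[j, ], `-`)^2)
      mind <- pmin(mind, dj)
    }
  }
  for (it in seq_len(iter)) {
    d2 <- vapply(seq_len(k),
                 function(j) rowSums(sweep(x, 2L, centers[j, ], `-`)^2),
                 numeric(n))
    lab <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      rows <- lab == j
      if (any(rows)) {
        centers[j, ] <- colMeans(x[rows, , drop = FALSE])
      } else {
        # re-seed an empty cluster at the point farthest from its center
        far <- which.max(rowSums((x - centers[lab, , drop = FALSE])^2))
        centers[j, ] <- x[far, ]
      }
    }
  }
  list(centers = centers, labels = max.col(
    -vapply(seq_len(k),
            function(j) rowSums(sweep(x, 2L, centers[j, ], `-`)^2),
            numeric(n)),
    ties.method = "first"))
}

#' Fit a diagonal-covariance Gaussian mixture by expectation-maximization
#'
#' Alternates an E-step (posterior component responsibilities under the
#' current parameters) and an M-step (weighted maximum-likelihood update of
#' the mixing weights, component means and per-dimension variances) until
#' the total log-likelihood improves by less than `tol` or `max_iter`
#' E-steps have run. Initialization is a farthest-point k-means seeding
#' (10 Lloyd iterations) driven by `seed`, so fits are exactly reproducible.
#' Per-dimension variances are floored at `var_floor_frac` times the data
#' variance, which keeps degenerate (constant or single-point) components
#' finite.
#'
#' @param x Numeric matrix, one row per observation (rownames become
#'   observation labels).
#' @param k Number of mixture components (`1 <= k <= nrow(x)`).
#' @param seed RNG seed for the initialization.
#' @param tol Convergence threshold on the log-likelihood improvement.
#' @param max_iter Maximum number of E-steps.
#' @param var_floor_frac Variance floor as a fraction of the per-dimension
#'   data variance.
#' @return An object of class `"gmm_fit"`: component `weights`, `means`
#'   (`k x d`), `variances` (`k x d`), `responsibilities` (`n x k`),
#'   `labels` (named argmax assignments, ties to the lowest index),
#'   `loglik`, `loglik_trace`, `converged`, `iterations`, plus bookkeeping.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(60), 30), matrix(rnorm(60, 6), 30))
#' fit <- gmm_fit(x, k = 2, seed = 1)
#' table(fit$labels)
#' @export
gmm_fit <- function(x, k, seed = 1, tol = 1e-6, max_iter = 100,
                    var_floor_frac = 1e-6) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  d <- ncol(x)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > n) stop("k (", k, ") exceeds the number of rows (", n, ")", call. = FALSE)
  floor_d <- .variance_floor(x, var_floor_frac)

  init <- .with_seed(seed, .kmeans_init(x, k))
  means <- init$centers
  weights <- tabulate(init$labels, k) / n
  weights <- pmax(weights, 1 / (10 * n))
  weights <- weights / sum(weights)
  variances <- matrix(0, k, d)
  for (j in seq_len(k)) {
    rows <- init$labels == j
    vj <- if (sum(rows) > 1L) {
      apply(x[rows, , drop = FALSE], 2L, stats::var) * (sum(rows) - 1) / sum(rows)
    } else {
      apply(x, 2L, stats::var) * (n - 1) / n
    }
    variances[j, ] <- pmax(vj, floor_d)
  }

  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  resp <- NULL
  it <- 0L
  repeat {
    it <- it + 1L
    ld <- .log_dens(x, means, variances)
    ld <- sweep(ld, 2L, log(weights), `+`)
    lse <- .logsumexp_rows(ld)
    ll <- sum(lse)
    resp <- exp(ld - lse)
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && ll - ll_prev < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    ll_prev <- ll
    nk <- pmax(colSums(resp), 1e-12)
    weights <- nk / n
    means <- crossprod(resp, x) / nk
    ex2 <- crossprod(resp, x^2) / nk
    variances <- pmax(ex2 - means^2, rep(floor_d, each = k))
  }

  labels <- max.col(resp, ties.method = "first")
  names(labels) <- rownames(x)
  structure(
    list(
      k = k, weights = as.numeric(weights), means = means,
      variances = variances, responsibilities = resp, labels = labels,
      loglik = trace[length(trace)], loglik_trace = trace,
      converged = converged, iterations = it,
      n = n, d = d, seed = seed, var_floor = floor_d,
      call = match.call()
    ),
    class = "gmm_fit"
  )
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("Diagonal-covariance Gaussian mixture (EM)\n")
  cat("  components:", x$k, "  observations:", x$n, "  dimensions:", x$d, "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      if (x$converged) "(converged" else "(max iterations",
      paste0("after ", x$iterations, " E-steps)"), "\n")
  cat("  weights:", paste(format(x$weights, digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.gmm_fit <- function(object, ...) {
  out <- list(
    k = object$k,
    weights = object$weights,
    cluster_sizes = tabulate(object$labels, object$k),
    loglik = object$loglik,
    iterations = object$iterations,
    converged = object$converged
  )
  class(out) <- "summary.gmm_fit"
  out
}

#' @export
print.summary.gmm_fit <- function(x, ...) {
  cat("Gaussian mixture summary: k =", x$k, "\n")
  cat("  cluster sizes:", paste(x$cluster_sizes, collapse = " "), "\n")
  cat("  weights:", paste(format(x$weights, digits = 3), collapse = " "), "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8), "after",
      x$iterations, "E-steps;", if (x$converged) "converged" else "not converged", "\n")
  invisible(x)
}

#' @export
logLik.gmm_fit <- function(object, ...) {
  structure(object$loglik,
            df = (object$k - 1) + 2 * object$k * object$d,
            nobs = object$n, class = "logLik")
}

#' @export
coef.gmm_fit <- function(object, ...) {
  list(weights = object$weights, means = object$means,
       variances = object$variances)
}

#' Posterior responsibilities or hard labels for new data
#'
#' @param object A [gmm_fit()] result.
#' @param newdata Numeric matrix with the same number of columns as the
#'   training data (defaults to the training data).
#' @param type `"class"` for argmax labels, `"responsibility"` for the
#'   posterior matrix.
#' @param ... Unused.
#' @export
predict.gmm_fit <- function(object, newdata = NULL, type = c("class", "responsibility"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    resp <- object$responsibilities
  } else {
    newdata <- as.matrix(newdata)
    ld <- .log_dens(newdata, object$means, object$variances)
    ld <- sweep(ld, 2L, log(object$weights), `+`)
    resp <- exp(ld - .logsumexp_rows(ld))
  }
  if (type == "responsibility") resp else max.col(resp, ties.method = "first")
}

#' Draw observations from a fitted mixture
#'
#' @param object A [gmm_fit()] result.
#' @param nsim Number of observations.
#' @param seed RNG seed.
#' @param ... Unused.
#' @return Numeric matrix `nsim x d` with a `"component"` attribute.
#' @export
simulate.gmm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() {
    comp <- sample.int(object$k, nsim, replace = TRUE, prob = object$weights)
    z <- matrix(stats::rnorm(nsim * object$d), nsim, object$d)
    out <- object$means[comp, , drop = FALSE] +
      z * sqrt(object$variances[comp, , drop = FALSE])
    attr(out, "component") <- comp
    out
  }
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

# Total held-out log-likelihood of `x` under a fitted mixture.
.heldout_loglik <- function(fit, x) {
  ld <- .log_dens(as.matrix(x), fit$means, fit$variances)
  ld <- sweep(ld, 2L, log(fit$weights), `+`)
  sum(.logsumexp_rows(ld))
}

#' Choose the number of mixture components by cross-validated likelihood
#'
#' Starting at `k = 1`, the component count is increased while the mean
#' held-out log-likelihood over `folds` cross-validation folds improves;
#' the last improving `k` is returned (capped at `k_max`). This emulates
#' automatic class-number selection by cross-validation as implemented in
#' common EM clustering toolkits.
#'
#' @param x Numeric feature matrix.
#' @param folds Number of cross-validation folds (default 10; must not
#'   exceed the number of rows).
#' @param seed RNG seed driving fold assignment and the inner fits.
#' @param k_max Upper bound on the component count.
#' @param ... Passed to [gmm_fit()] (`tol`, `max_iter`, `var_floor_frac`).
#' @return Integer component count.
#' @export
select_k <- function(x, folds = 10, seed = 1, k_max = 10, ...) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < folds) {
    stop("fewer rows (", n, ") than folds (", folds, ")", call. = FALSE)
  }
  fold_id <- .with_seed(.sub_seed(seed, 0, 3), sample(rep(seq_len(folds), length.out = n)))
  max_fold <- max(tabulate(factor(fold_id, levels = seq_len(folds))))
  k_cap <- min(k_max, n - max_fold)  # every training split must hold >= k rows
  cv_ll <- function(k) {
    total <- 0
    for (f in seq_len(folds)) {
      train <- x[fold_id != f, , drop = FALSE]
      test <- x[fold_id == f, , drop = FALSE]
      if (!nrow(test)) next
      fit <- tryCatch(
        gmm_fit(train, k, seed = .sub_seed(seed, k * 1000 + f, 5), ...),
        error = function(e) NULL
      )
      if (is.null(fit)) return(-Inf)
      total <- total + .heldout_loglik(fit, test)
    }
    total
  }
  best_k <- 1L
  best_ll <- cv_ll(1L)
  while (best_k < k_cap) {
    cand <- cv_ll(best_k + 1L)
    if (cand > best_ll) {
      best_k <- best_k + 1L
      best_ll <- cand
    } else {
      break
    }
  }
  best_k
}

#' Candidates sharing the approved drugs' cluster
#'
#' Under policy `"all"` every drug must land in one cluster (a violation
#' raises a condition of class `"cocluster_violation"` carrying the drug
#' partition); under the default `"plurality"` the cluster holding the most
#' drugs wins, ties broken toward the lower cluster index. Non-drug members
#' of the chosen cluster are returned.
#'
#' @param labels Named integer vector of cluster assignments (names are
#'   compound ids, as in `gmm_fit()$labels`).
#' @param drugs Integer vector of drug CIDs (all must be present in
#'   `labels`).
#' @param policy `"plurality"` or `"all"`.
#' @return Sorted integer vector of co-clustered candidate CIDs.
#' @export
cocluster_select <- function(labels, drugs, policy = c("plurality", "all")) {
  policy <- match.arg(policy)
  ids <- names(labels)
  if (is.null(ids)) stop("labels must be named by compound id", call. = FALSE)
  drug_rows <- ids %in% as.character(drugs)
  if (sum(drug_rows) < length(unique(drugs))) {
    stop("assignment does not cover all drugs", call. = FALSE)
  }
  drug_clusters <- labels[drug_rows]
  if (policy == "all") {
    if (length(unique(drug_clusters)) > 1L) {
      tab <- table(drug_clusters)
      cond <- structure(
        class = c("cocluster_violation", "error", "condition"),
        list(message = paste0("approved drugs split across clusters: ",
                              paste(names(tab), tab, sep = ":", collapse = ", ")),
             call = sys.call(-1), partition = drug_clusters)
      )
      stop(cond)
    }
    target <- unique(drug_clusters)
  } else {
    tab <- tabulate(drug_clusters)
    target <- which.max(tab)  # ties -> lowest cluster index
  }
  sort(as.integer(ids[!drug_rows & labels == target]))
}

#' Iterative co-clustering refinement
#'
#' Repeats encode -> select k -> EM fit -> co-cluster selection on the
#' surviving candidates plus the approved drugs, stopping when the
#' candidate set stops shrinking, becomes empty, or `rounds` is reached.
#' Each round re-encodes only the survivors, so the mixture is refit on an
#' increasingly drug-like cohort.
#'
#' @param candidates Integer vector of candidate CIDs entering round 1.
#' @param inputs A [screen_inputs()] object.
#' @param index A [build_index()] result.
#' @param rounds Maximum number of rounds (default 2).
#' @param folds,k_max Passed to [select_k()] (folds are clamped to the
#'   cohort size).
#' @param policy Passed to [cocluster_select()].
#' @param seed Base RNG seed; each round derives its own substream.
#' @param ... Passed to [gmm_fit()].
#' @return A list: `candidates` (final survivor CIDs) and `audit` (data
#'   frame with one row per executed round: cohort size, chosen `k`,
#'   cluster sizes, survivor count).
#' @export
iterative_refine <- function(candidates, inputs, index, rounds = 2,
                             folds = 10, k_max = 10,
                             policy = c("plurality", "all"), seed = 1, ...) {
  policy <- match.arg(policy)
  current <- sort(unique(as.integer(candidates)))
  audit <- data.frame(round = integer(0), n_candidates = integer(0),
                      k = integer(0), cluster_sizes = character(0),
                      n_survivors = integer(0))
  if (rounds < 1) return(list(candidates = current, audit = audit))
  for (r in seq_len(rounds)) {
    if (!length(current)) break
    cohort <- encode_cohort(current, inputs, index)
    n <- nrow(cohort$features)
    k <- select_k(cohort$features, folds = min(folds, n),
                  seed = .sub_seed(seed, r, 7), k_max = min(k_max, n), ...)
    fit <- gmm_fit(cohort$features, k, seed = .sub_seed(seed, r, 11), ...)
    survivors <- cocluster_select(fit$labels, inputs$drugs, policy)
    audit <- rbind(audit, data.frame(
      round = r, n_candidates = length(current), k = k,
      cluster_sizes = paste(tabulate(fit$labels, k), collapse = ","),
      n_survivors = length(survivors)
    ))
    if (setequal(survivors, current)) {
      current <- survivors
      break  # fixpoint: the candidate set stopped shrinking
    }
    current <- survivors
  }
  list(candidates = current, audit = audit)
}
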