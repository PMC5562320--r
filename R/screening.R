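# Step 1 and step 2 of the screen: preliminary interaction screen against
# the approved drugs, association test against disease-related chemicals
# and genes, and the permutation test that turns rating scores into
# empirical P-values with thresholds derived from the drugs themselves.

# Deterministic substream seed for one compound within one run; keeps every
# seed below 2^31 - 1.
.sub_seed <- function(seed, compound, offset = 0) {
  as.integer((as.double(seed) %% 2147483647 * 16807 +
                as.double(compound) * 2 + offset) %% 2147483647)
}

# Evaluate `expr` under a local RNG state; the caller's stream is restored.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Preliminary screen: compounds interacting with at least one approved drug
#'
#' Returns every compound in the chemical universe that shares a
#' positive-combined chemical link with at least one approved drug. The
#' drugs themselves are excluded from the result.
#'
#' @param index A [build_index()] result.
#' @param drugs Integer vector of approved-drug CIDs.
#' @return Sorted integer vector of candidate CIDs.
#' @export
preliminary_screen <- function(index, drugs) {
  if (!length(drugs)) stop("empty drug set", call. = FALSE)
  hits <- unlist(lapply(drugs, function(d) chem_neighbors(index, d)$neighbor),
                 use.names = FALSE)
  sort(setdiff(unique(hits), drugs))
}

#' Rating score: mean combined score against a reference set
#'
#' The rating score of compound `c` against a reference set is the mean
#' `combined` score over the links that exist between `c` and members of
#' the set, and 0 when no such link exists. For `mode = "chemicals"` the
#' reference is a set of compound ids matched against chemical links; for
#' `mode = "genes"` it is a set of protein ids matched against
#' protein-chemical links (each linked protein counted once).
#'
#' @param c Compound id.
#' @param reference Integer CIDs (`mode = "chemicals"`) or character
#'   protein ids (`mode = "genes"`).
#' @param index A [build_index()] result.
#' @param mode `"chemicals"` or `"genes"`.
#' @return Non-negative scalar on the 0-1000 score scale.
#' @export
rating_score <- function(c, reference, index, mode = c("chemicals", "genes")) {
  mode <- match.arg(mode)
  if (mode == "chemicals") {
    nb <- chem_neighbors(index, c)
    sc <- nb$combined[nb$neighbor %in% reference]
  } else {
    pp <- protein_partners(index, c)
    sc <- pp$combined[pp$protein %in% reference]
  }
  if (length(sc)) mean(sc) else 0
}

#' Association test against disease chemicals and genes
#'
#' Computes both rating scores for each candidate and retains exactly the
#' candidates that interact with at least one disease-related chemical and
#' at least one disease-related gene (`rs_chemicals > 0` and
#' `rs_genes > 0`). The same rule is applied to the approved drugs when
#' they are assessed for threshold derivation: drugs failing it drop out of
#' the reference cohort.
#'
#' @param candidates Integer vector of compound ids (typically from
#'   [preliminary_screen()], or the drug set itself).
#' @param inputs A [screen_inputs()] object.
#' @param index A [build_index()] result.
#' @return Data frame with columns `compound`, `rs_chemicals`, `rs_genes`,
#'   `pvalue_chemicals`, `pvalue_genes` (P-values `NA` until
#'   [assess_pvalues()] fills them), one row per retained candidate, sorted
#'   by compound id.
#' @export
association_test <- function(candidates, inputs, index) {
  candidates <- sort(unique(as.integer(candidates)))
  rs_c <- vapply(candidates, rating_score, numeric(1),
                 reference = inputs$disease_chemicals, index = index,
                 mode = "chemicals")
  rs_g <- vapply(candidates, rating_score, numeric(1),
                 reference = inputs$disease_proteins, index = index,
                 mode = "genes")
  keep <- rs_c > 0 & rs_g > 0
  data.frame(
    compound = candidates[keep],
    rs_chemicals = rs_c[keep],
    rs_genes = rs_g[keep],
    pvalue_chemicals = NA_real_,
    pvalue_genes = NA_real_
  )
}

#' Permutation-test configuration
#'
#' @param universe Vector of ids (compound CIDs or protein ids) random
#'   reference sets are drawn from.
#' @param n_permutations Number of random sets (default 1000).
#' @param seed Base RNG seed for the run; each compound gets a
#'   deterministically derived substream unless `shared_sets` is set.
#' @param exhaustive Enumerate every subset instead of sampling (only
#'   sensible on tiny universes).
#' @param shared_sets Draw one collection of random sets from `seed` and
#'   reuse it for every compound (the assessed compound is then not removed
#'   from the sampling frame, so the sets stay identical; a drawn self-id
#'   contributes nothing because compounds carry no self links).
#' @return An object of class `"permutation_config"`.
#' @export
permutation_config <- function(universe, n_permutations = 1000, seed = 1,
                               exhaustive = FALSE, shared_sets = FALSE) {
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  if (!length(universe)) stop("empty permutation universe", call. = FALSE)
  structure(
    list(universe = universe, n_permutations = as.integer(n_permutations),
         seed = as.integer(seed), exhaustive = isTRUE(exhaustive),
         shared_sets = isTRUE(shared_sets)),
    class = "permutation_config"
  )
}

# Mean combined score of c against positions of a sampled set, given a
# score lookup aligned to the universe (NA where c has no link).
.set_score <- function(score_by_pos, pos) {
  v <- score_by_pos[pos]
  v <- v[!is.na(v)]
  if (length(v)) mean(v) else 0
}

#' Empirical P-value of a rating score by permutation
#'
#' Draws `n_permutations` random reference sets of size `reference_size`
#' without replacement from the configured universe, scores compound `c`
#' against each with [rating_score()] semantics, and returns
#' `W / n_permutations` where `W` counts the sets whose rating score is
#' strictly larger than `observed_rs` (ties do not count). In exhaustive
#' mode every subset is enumerated and the exact fraction is returned.
#'
#' @param c Compound id.
#' @param observed_rs Observed rating score of `c` against the real
#'   reference set.
#' @param reference_size Size of the reference set being emulated.
#' @param cfg A [permutation_config()].
#' @param index A [build_index()] result.
#' @param mode `"chemicals"` or `"genes"` (selects the link table and the
#'   id type of the universe).
#' @return Empirical P-value in `[0, 1]`, a multiple of
#'   `1 / n_permutations` (or exact in exhaustive mode).
#' @export
permute_pvalue <- function(c, observed_rs, reference_size, cfg, index,
                           mode = c("chemicals", "genes")) {
  mode <- match.arg(mode)
  universe <- cfg$universe
  if (mode == "chemicals" && !cfg$shared_sets) {
    universe <- universe[universe != c]
  }
  U <- length(universe)
  if (reference_size > U) {
    stop("reference_size (", reference_size, ") exceeds universe size (", U, ")",
         call. = FALSE)
  }
  if (mode == "chemicals") {
    nb <- chem_neighbors(index, c)
    ids <- nb$neighbor
    sc <- nb$combined
  } else {
    pp <- protein_partners(index, c)
    ids <- pp$protein
    sc <- pp$combined
  }
  score_by_pos <- rep(NA_real_, U)
  hit <- match(ids, universe)
  ok <- !is.na(hit)
  score_by_pos[hit[ok]] <- sc[ok]

  if (cfg$exhaustive) {
    scores <- utils::combn(U, reference_size,
                           FUN = function(pos) .set_score(score_by_pos, pos))
    return(sum(scores > observed_rs) / length(scores))
  }
  seed <- if (cfg$shared_sets) cfg$seed
          else .sub_seed(cfg$seed, c, offset = if (mode == "chemicals") 0 else 1)
  B <- cfg$n_permutations
  .with_seed(seed, {
    w <- 0L
    for (b in seq_len(B)) {
      if (.set_score(score_by_pos, sample.int(U, reference_size)) > observed_rs) {
        w <- w + 1L
      }
    }
    w / B
  })
}

#' Fill permutation P-values into an assessment table
#'
#' Runs [permute_pvalue()] for both channels of every compound in an
#' [association_test()] result. Chemical-channel sets are drawn from the
#' chemical universe (minus the assessed compound), gene-channel sets from
#' the protein universe, with set sizes equal to the disease-chemical count
#' and the disease-gene count respectively.
#'
#' @param assessments Data frame from [association_test()].
#' @param inputs A [screen_inputs()] object.
#' @param index A [build_index()] result.
#' @param n_permutations Random sets per compound and channel (default 1000).
#' @param seed Base seed for the run.
#' @param shared_sets Reuse one collection of sets across compounds.
#' @return The assessment data frame with `pvalue_chemicals` and
#'   `pvalue_genes` filled in.
#' @export
assess_pvalues <- function(assessments, inputs, index, n_permutations = 1000,
                           seed = 1, shared_sets = FALSE) {
  cfg_c <- permutation_config(index$chemical_universe, n_permutations, seed,
                              shared_sets = shared_sets)
  cfg_g <- permutation_config(index$protein_universe, n_permutations, seed,
                              shared_sets = shared_sets)
  n_chem <- length(inputs$disease_chemicals)
  n_gene <- length(inputs$gene_map)
  assessments$pvalue_chemicals <- mapply(
    permute_pvalue, assessments$compound, assessments$rs_chemicals,
    MoreArgs = list(reference_size = n_chem, cfg = cfg_c, index = index,
                    mode = "chemicals")
  )
  assessments$pvalue_genes <- mapply(
    permute_pvalue, assessments$compound, assessments$rs_genes,
    MoreArgs = list(reference_size = n_gene, cfg = cfg_g, index = index,
                    mode = "genes")
  )
  assessments
}

#' Derive P-value thresholds from the approved drugs
#'
#' To retain as many candidates as possible without admitting compounds
#' less disease-associated than the approved drugs themselves, the
#' per-channel threshold is the maximum P-value observed among the drugs
#' that passed the association test.
#'
#' @param drug_assessments Assessment data frame for the drugs, P-values
#'   filled.
#' @return Named numeric vector `c(chemicals = ..., genes = ...)`.
#' @export
select_thresholds <- function(drug_assessments) {
  if (!nrow(drug_assessments)) stop("no drug assessments", call. = FALSE)
  if (anyNA(drug_assessments$pvalue_chemicals) ||
      anyNA(drug_assessments$pvalue_genes)) {
    stop("drug assessments carry unset P-values", call. = FALSE)
  }
  c(chemicals = max(drug_assessments$pvalue_chemicals),
    genes = max(drug_assessments$pvalue_genes))
}

#' Filter an assessment table by P-value thresholds
#'
#' Retains compounds whose P-values are less than or equal to the
#' per-channel thresholds (boundary inclusive) on both channels.
#'
#' @param assessments Assessment data frame, P-values filled.
#' @param thresholds Numeric vector of length 2, `(chemicals, genes)` (the
#'   [select_thresholds()] output).
#' @return The retained rows.
#' @export
apply_thresholds <- function(assessments, thresholds) {
  keep <- assessments$pvalue_chemicals <= thresholds[[1]] &
    assessments$pvalue_genes <= thresholds[[2]]
  out <- assessments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
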