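# Synthetic STITCH-dialect fixture bundles with planted ground truth.
#
# The generator emulates the five inputs of a screening run: chemical and
# protein link tables, an approved-drug list, a disease-chemical set and a
# gene-to-protein map. Compounds are planted with known fates:
#   positive            - survives all three steps (drug-like profile:
#                         same score distributions as the drugs against
#                         drugs / disease chemicals / genes, but more
#                         low-score background links, which pushes its
#                         permutation P-values well below the drug-derived
#                         thresholds)
#   decoy_no_drug       - no link to any approved drug (fails step 1)
#   decoy_no_gene       - no protein link to a disease gene (fails the
#                         association test)
#   decoy_nonspecific   - uniform average-strength links to ~30% of the
#                         universe, so its observed rating score sits at
#                         the permutation null's mean (P ~ 0.5, fails the
#                         permutation test)
#   background          - sparse random links, fate not constrained

#' Specification of a synthetic fixture bundle
#'
#' Counts default to a screen-sized problem: 200 candidate compounds of
#' which 8 are planted positives and 10 + 10 + 10 are decoys of the three
#' classes, 10 approved drugs, 40 disease-related chemicals and 15
#' disease-related genes. `score_distribution` carries the integer score
#' ranges (STITCH 0-1000 scale, customary floor 150): `strong` for
#' drug-drug-like links, `mid` for disease-chemical/gene links, `weak` for
#' background links, `nonspecific` for the nonspecific decoys, and the
#' per-channel `dropout` probability that a non-combined channel is 0.
#'
#' @param n_compounds Number of candidate (non-drug) compounds.
#' @param n_drugs Number of approved drugs.
#' @param n_disease_chemicals Size of the disease-chemical set.
#' @param n_genes Number of disease-related genes.
#' @param n_planted_positives,n_decoys_no_drug,n_decoys_no_gene,n_decoys_nonspecific
#'   Planted-class counts (their sum must not exceed `n_compounds`).
#' @param score_distribution List of score ranges and dropout, see above.
#' @param seed RNG seed; the whole bundle is a deterministic function of
#'   the spec plus this seed.
#' @return An object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(n_compounds = 200, n_drugs = 10,
                         n_disease_chemicals = 40, n_genes = 15,
                         n_planted_positives = 8, n_decoys_no_drug = 10,
                         n_decoys_no_gene = 10, n_decoys_nonspecific = 10,
                         score_distribution = list(
                           strong = c(600L, 950L), mid = c(400L, 800L),
                           weak = c(150L, 300L), nonspecific = c(350L, 650L),
                           dropout = 0.3
                         ),
                         seed = 1) {
  counts <- c(n_compounds, n_drugs, n_disease_chemicals, n_genes,
              n_planted_positives, n_decoys_no_drug, n_decoys_no_gene,
              n_decoys_nonspecific)
  if (any(counts < 0)) stop("fixture counts must be >= 0", call. = FALSE)
  planted <- n_planted_positives + n_decoys_no_drug + n_decoys_no_gene +
    n_decoys_nonspecific
  if (planted > n_compounds) {
    stop("planted classes (", planted, ") exceed n_compounds (", n_compounds, ")",
         call. = FALSE)
  }
  structure(
    list(n_compounds = n_compounds, n_drugs = n_drugs,
         n_disease_chemicals = n_disease_chemicals, n_genes = n_genes,
         n_planted_positives = n_planted_positives,
         n_decoys_no_drug = n_decoys_no_drug,
         n_decoys_no_gene = n_decoys_no_gene,
         n_decoys_nonspecific = n_decoys_nonspecific,
         score_distribution = score_distribution, seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

# integer score drawn uniformly from a range
.rscore <- function(n, range) {
  as.integer(floor(stats::runif(n, range[1], range[2] + 1)))
}

# secondary channels near the combined score, with dropout
.rchannels <- function(combined, dropout) {
  k <- length(combined)
  out <- matrix(0L, k, 4L)
  for (j in 1:4) {
    jitter <- as.integer(round(stats::runif(k, -150, 150)))
    v <- pmin(pmax(combined + jitter, 1L), 1000L)
    v[stats::runif(k) < dropout] <- 0L
    out[, j] <- v
  }
  out
}

#' Generate a synthetic fixture bundle
#'
#' Writes the five input files consumed by the screening pipeline plus a
#' ground-truth manifest into `dir`, all as plain TSV/text. The chemical
#' links file uses STITCH-style `CIDm<8 digits>` identifiers and lists the
#' drug-drug links in both orientations (exercising the undirected merge);
#' the protein links file carries organism-prefixed protein ids and a few
#' non-target-organism rows (exercising the organism filter).
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if missing).
#' @return An object of class `"fixture_bundle"`: `paths` (named list of
#'   the six files), `manifest` (data frame of compound, planted_fate) and
#'   `spec`.
#' @export
generate_fixture <- function(spec, dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sd_ <- spec$score_distribution

  drugs <- 100L + seq_len(spec$n_drugs)
  disease_chems <- 5000L + seq_len(spec$n_disease_chemicals)
  compounds <- 1000L + seq_len(spec$n_compounds)
  i <- 0L
  positives <- compounds[seq_len(spec$n_planted_positives)]
  i <- i + spec$n_planted_positives
  no_drug <- compounds[i + seq_len(spec$n_decoys_no_drug)]
  i <- i + spec$n_decoys_no_drug
  no_gene <- compounds[i + seq_len(spec$n_decoys_no_gene)]
  i <- i + spec$n_decoys_no_gene
  nonspecific <- compounds[i + seq_len(spec$n_decoys_nonspecific)]
  i <- i + spec$n_decoys_nonspecific
  background <- compounds[(i + 1):length(compounds)]
  if (i >= length(compounds)) background <- integer(0)

  genes <- sprintf("GENE%03d", seq_len(spec$n_genes))
  gene_protein_counts <- 1L + seq_len(spec$n_genes) %% 2L
  gene_proteins <- split(
    sprintf("ENSP%08d", seq_len(sum(gene_protein_counts))),
    rep(seq_len(spec$n_genes), gene_protein_counts)
  )
  names(gene_proteins) <- genes
  all_gene_proteins <- unlist(gene_proteins, use.names = FALSE)
  bg_proteins <- sprintf("ENSP%08d", length(all_gene_proteins) + seq_len(4L * spec$n_genes))

  chem_seen <- new.env(parent = emptyenv())
  chem_rows <- vector("list", 4096L)
  n_chem <- 0L
  add_chem <- function(a, b, range) {
    for (idx in seq_along(b)) {
      x <- a
      y <- b[idx]
      if (x == y) next
      key <- paste(min(x, y), max(x, y), sep = "_")
      if (exists(key, envir = chem_seen, inherits = FALSE)) next
      assign(key, TRUE, envir = chem_seen)
      n_chem <<- n_chem + 1L
      comb <- .rscore(1L, range)
      chem_rows[[n_chem]] <<- c(min(x, y), max(x, y), .rchannels(comb, sd_$dropout), comb)
    }
  }
  prot_seen <- new.env(parent = emptyenv())
  prot_rows <- vector("list", 4096L)
  n_prot <- 0L
  add_prot <- function(c, proteins, range) {
    for (p in proteins) {
      key <- paste(p, c, sep = "_")
      if (exists(key, envir = prot_seen, inherits = FALSE)) next
      assign(key, TRUE, envir = prot_seen)
      n_prot <<- n_prot + 1L
      comb <- .rscore(1L, range)
      prot_rows[[n_prot]] <<- list(p, c, .rchannels(comb, sd_$dropout), comb)
    }
  }
  add_gene_links <- function(c, n, range) {
    gs <- sample(genes, min(n, length(genes)))
    add_prot(c, unlist(gene_proteins[gs], use.names = FALSE), range)
  }

  .with_seed(spec$seed, {
    # drugs: a ring of strong drug-drug links plus one extra partner each,
    # mid-strength links to 40% of the disease chemicals, a handful of
    # weak background links, and mid-strength links to 5 genes (plus 3
    # weak background-protein links)
    n_dr_dis <- max(1L, round(0.4 * length(disease_chems)))
    for (j in seq_along(drugs)) {
      d <- drugs[j]
      if (length(drugs) > 1L) {
        add_chem(d, drugs[j %% length(drugs) + 1L], sd_$strong)
        add_chem(d, sample(setdiff(drugs, d), 1L), sd_$strong)
      }
      add_chem(d, sample(disease_chems, n_dr_dis), sd_$mid)
      if (length(background)) add_chem(d, sample(background, 6L), sd_$weak)
      add_gene_links(d, 5L, sd_$mid)
      add_prot(d, sample(bg_proteins, 3L), sd_$weak)
    }
    # planted positives: drug-like profile (same ranges as the drugs) with
    # more weak background links, which is what drives their permutation
    # P-values below the drug-derived thresholds
    n_pos_dis <- max(1L, round(0.5 * length(disease_chems)))
    for (c in positives) {
      add_chem(c, sample(drugs, min(4L, length(drugs))), sd_$strong)
      add_chem(c, sample(disease_chems, n_pos_dis), sd_$mid)
      if (length(background)) add_chem(c, sample(background, 15L), sd_$weak)
      add_gene_links(c, 5L, sd_$mid)
      add_prot(c, sample(bg_proteins, 10L), sd_$weak)
    }
    # decoys failing step 1: positive-like but never linked to a drug
    for (c in no_drug) {
      add_chem(c, sample(disease_chems, n_pos_dis), sd_$mid)
      if (length(background)) add_chem(c, sample(background, 10L), sd_$weak)
      add_gene_links(c, 4L, sd_$mid)
    }
    # decoys failing the association test: drug-linked but no gene link
    for (c in no_gene) {
      add_chem(c, sample(drugs, min(2L, length(drugs))), sd_$strong)
      add_chem(c, sample(disease_chems, n_pos_dis), sd_$mid)
      if (length(background)) add_chem(c, sample(background, 10L), sd_$weak)
    }
    # nonspecific decoys: average-strength links to ~30% of the non-drug
    # universe plus forced drug/gene links, so they pass steps 1-2.1, while
    # their real (strong) functional neighborhood lies outside the disease
    # sets -- random reference sets catch those strong partners, so the
    # observed rating score sits in the lower tail of the permutation null
    nonspecific_pool <- c(compounds, disease_chems)
    for (c in nonspecific) {
      if (length(background)) add_chem(c, sample(background, 15L), sd_$strong)
      add_prot(c, sample(bg_proteins, 12L), sd_$strong)
      targets <- sample(setdiff(nonspecific_pool, c),
                        round(0.3 * length(nonspecific_pool)))
      add_chem(c, targets, sd_$nonspecific)
      add_chem(c, sample(drugs, 1L), sd_$nonspecific)
      add_gene_links(c, 3L, sd_$nonspecific)
      add_prot(c, sample(bg_proteins, round(0.3 * length(bg_proteins))),
               sd_$nonspecific)
    }
    # background: sparse random links; a third get a drug link, half get a
    # disease-chemical link, a sixth get a gene link
    for (c in background) {
      add_chem(c, sample(setdiff(c(compounds, disease_chems), c), 3L),
               c(sd_$weak[1], sd_$mid[2]))
      if (stats::runif(1) < 0.3) add_chem(c, sample(drugs, 1L), sd_$mid)
      if (stats::runif(1) < 0.5) add_chem(c, sample(disease_chems, 2L), sd_$weak)
      if (stats::runif(1) < 1 / 6) add_gene_links(c, 1L, sd_$mid)
      if (stats::runif(1) < 0.3) add_prot(c, sample(bg_proteins, 2L), sd_$weak)
    }
  })

  chem <- do.call(rbind, chem_rows[seq_len(n_chem)])
  chem_df <- data.frame(
    chemical_a = sprintf("CIDm%08d", chem[, 1]),
    chemical_b = sprintf("CIDm%08d", chem[, 2]),
    similarity = chem[, 3], experimental = chem[, 4], database = chem[, 5],
    textmining = chem[, 6], combined_score = chem[, 7]
  )
  # drug-drug links also in the reverse orientation (identical scores):
  # the reader must merge them without warnings
  ring <- chem_df[chem[, 1] %in% drugs & chem[, 2] %in% drugs, , drop = FALSE]
  if (nrow(ring)) {
    rev_ring <- ring[, c(2, 1, 3:7)]
    names(rev_ring) <- names(ring)
    chem_df <- rbind(chem_df, rev_ring)
  }

  prot_df <- do.call(rbind, lapply(prot_rows[seq_len(n_prot)], function(r) {
    data.frame(protein = paste0("9606.", r[[1]]),
               chemical = sprintf("CIDm%08d", r[[2]]),
               experimental = r[[3]][1], prediction = r[[3]][2],
               database = r[[3]][3], textmining = r[[3]][4],
               combined_score = r[[4]])
  }))
  # a few non-target-organism rows the reader must drop
  decoy_org <- data.frame(
    protein = paste0("10090.ENSMUSP", sprintf("%08d", 1:3)),
    chemical = sprintf("CIDm%08d", compounds[seq_len(min(3, length(compounds)))]),
    experimental = 500L, prediction = 0L, database = 500L,
    textmining = 0L, combined_score = 500L
  )
  prot_df <- rbind(prot_df, decoy_org)

  manifest <- data.frame(
    compound = c(drugs, disease_chems, positives, no_drug, no_gene,
                 nonspecific, background),
    planted_fate = c(rep("drug", length(drugs)),
                     rep("disease_chemical", length(disease_chems)),
                     rep("positive", length(positives)),
                     rep("decoy_no_drug", length(no_drug)),
                     rep("decoy_no_gene", length(no_gene)),
                     rep("decoy_nonspecific", length(nonspecific)),
                     rep("background", length(background)))
  )

  paths <- list(
    chemical_links = file.path(dir, "chemical_links.tsv"),
    protein_links = file.path(dir, "protein_links.tsv"),
    drugs = file.path(dir, "drugs.txt"),
    disease_chemicals = file.path(dir, "disease_chemicals.txt"),
    gene_map = file.path(dir, "gene_map.tsv"),
    manifest = file.path(dir, "manifest.tsv")
  )
  utils::write.table(chem_df, paths$chemical_links, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(prot_df, paths$protein_links, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c("# approved drugs", sprintf("CID%d", drugs)), paths$drugs)
  writeLines(c("# disease-related chemicals", sprintf("CID%d", disease_chems)),
             paths$disease_chemicals)
  gm <- data.frame(
    gene = rep(names(gene_proteins), lengths(gene_proteins)),
    protein = unlist(gene_proteins, use.names = FALSE)
  )
  utils::write.table(gm, paths$gene_map, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(manifest, paths$manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  structure(list(paths = paths, manifest = manifest, spec = spec, dir = dir),
            class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("Synthetic fixture bundle in", x$dir, "\n")
  print(table(x$manifest$planted_fate))
  invisible(x)
}

#' Sample a labeled diagonal-Gaussian mixture
#'
#' Planted components have unit within-component standard deviation per
#' dimension and consecutive means separated by `separation` (in
#' within-component SD units, Euclidean distance); observations are split
#' evenly across components. Used as a test bed for [gmm_fit()] and
#' [select_k()].
#'
#' @param n Number of observations.
#' @param dims Dimensionality (default 15, matching the feature encoding).
#' @param k Number of planted components.
#' @param separation Distance between consecutive component means, in
#'   within-component SDs.
#' @param seed RNG seed.
#' @return A list: `data` (n x dims matrix), `labels` (true component of
#'   each row), `means` (k x dims planted means), `sd` (scalar 1).
#' @export
generate_gmm_data <- function(n, dims = 15, k = 2, separation = 5, seed = 1) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (separation <= 0) stop("separation must be > 0", call. = FALSE)
  means <- outer((seq_len(k) - 1) * separation / sqrt(dims), rep(1, dims))
  labels <- rep(seq_len(k), length.out = n)
  data <- .with_seed(seed, {
    means[labels, , drop = FALSE] + matrix(stats::rnorm(n * dims), n, dims)
  })
  list(data = data, labels = labels, means = means, sd = 1)
}
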