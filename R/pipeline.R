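# End-to-end orchestration: read the five inputs, run the three screening
# steps in order, derive thresholds from the approved drugs, iterate the
# co-clustering, and report per-stage counts plus the final putative
# compounds. Fully deterministic under a fixed seed.

#' Configuration of a screening run
#'
#' @param chemical_links,protein_links,drugs,disease_chemicals,gene_map
#'   Paths to the five input files (STITCH-dialect link tables, compound
#'   lists, gene-to-protein TSV). All must exist.
#' @param organism Organism code for the protein-links filter.
#' @param n_permutations Random sets per compound and channel.
#' @param seed Run seed; recorded in every output header.
#' @param thresholds Optional numeric length-2 override
#'   `(chemicals, genes)`; when `NULL` (default) thresholds are derived
#'   from the approved drugs' P-values.
#' @param folds,k_max,tol,max_iter,policy,rounds Clustering settings, see
#'   [select_k()], [gmm_fit()], [cocluster_select()], [iterative_refine()].
#' @param shared_sets Share the random permutation sets across compounds.
#' @param min_combined Combined-score cutoff applied when reading links.
#' @param out_dir Optional output directory for the stage TSVs.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(chemical_links, protein_links, drugs,
                       disease_chemicals, gene_map, organism = "9606",
                       n_permutations = 1000, seed = 1, thresholds = NULL,
                       folds = 10, k_max = 10, tol = 1e-6, max_iter = 100,
                       policy = "plurality", rounds = 2,
                       shared_sets = FALSE, min_combined = 0,
                       out_dir = NULL) {
  paths <- list(chemical_links = chemical_links, protein_links = protein_links,
                drugs = drugs, disease_chemicals = disease_chemicals,
                gene_map = gene_map)
  missing <- !vapply(paths, file.exists, logical(1))
  if (any(missing)) {
    stop("input file(s) not found: ",
         paste(unlist(paths[missing]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(thresholds) && length(thresholds) != 2) {
    stop("thresholds override must have length 2 (chemicals, genes)", call. = FALSE)
  }
  structure(
    list(paths = paths, organism = organism,
         n_permutations = as.integer(n_permutations), seed = as.integer(seed),
         thresholds = thresholds, folds = folds, k_max = k_max, tol = tol,
         max_iter = max_iter, policy = policy, rounds = rounds,
         shared_sets = isTRUE(shared_sets), min_combined = min_combined,
         out_dir = out_dir),
    class = "run_config"
  )
}

# Gene symbols whose mapped proteins carry a positive-combined link to c.
.linked_genes <- function(c, gene_map, index) {
  partners <- protein_partners(index, c)$protein
  names(gene_map)[vapply(gene_map, function(p) any(p %in% partners), logical(1))]
}

#' Run the full three-step screen
#'
#' Executes, in order: preliminary screening (compounds interacting with at
#' least one approved drug), the association test plus permutation test
#' (with thresholds derived from the approved drugs unless overridden), and
#' iterative EM co-clustering with the drugs in the 15-feature space. Any
#' stage yielding an empty set ends the run cleanly with the report up to
#' that stage.
#'
#' @param cfg A [run_config()].
#' @return An object of class `"screen_report"`: per-stage `counts`,
#'   `thresholds`, candidate `assessments` and `drug_assessments`, the
#'   clustering `audit`, the final `putative` table (assessment rows plus
#'   linked disease genes), and the `inputs`/`index` used.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  stage_msg <- function(...) message(sprintf("[%6.1fs] ", proc.time()[["elapsed"]] - t0), ...)

  tables <- interaction_tables(
    read_chemical_links(cfg$paths$chemical_links, cfg$min_combined),
    read_protein_links(cfg$paths$protein_links, cfg$organism, cfg$min_combined)
  )
  inputs <- screen_inputs(
    read_compound_list(cfg$paths$drugs),
    read_compound_list(cfg$paths$disease_chemicals),
    read_gene_map(cfg$paths$gene_map)
  )
  index <- build_index(tables)
  stage_msg("parsed ", nrow(tables$chemical_links), " chemical and ",
            nrow(tables$protein_links), " protein links")

  report <- structure(
    list(counts = c(universe = length(index$chemical_universe)),
         thresholds = NULL, assessments = NULL, drug_assessments = NULL,
         audit = NULL, putative = NULL, seed = cfg$seed, config = cfg,
         inputs = inputs, index = index),
    class = "screen_report"
  )

  prelim <- preliminary_screen(index, inputs$drugs)
  report$counts["preliminary"] <- length(prelim)
  stage_msg("preliminary screen: ", length(prelim), " compounds")
  if (!length(prelim)) return(report)

  assoc <- association_test(prelim, inputs, index)
  report$counts["association"] <- nrow(assoc)
  stage_msg("association test: ", nrow(assoc), " compounds")
  if (!nrow(assoc)) return(report)

  drug_assess <- association_test(inputs$drugs, inputs, index)
  drug_assess <- assess_pvalues(drug_assess, inputs, index,
                                cfg$n_permutations, cfg$seed, cfg$shared_sets)
  report$drug_assessments <- drug_assess
  thresholds <- if (is.null(cfg$thresholds)) {
    select_thresholds(drug_assess)
  } else {
    c(chemicals = cfg$thresholds[[1]], genes = cfg$thresholds[[2]])
  }
  report$thresholds <- thresholds
  stage_msg("thresholds: chemicals <= ", thresholds[["chemicals"]],
            ", genes <= ", thresholds[["genes"]],
            " (", nrow(drug_assess), " drugs in reference cohort)")

  assoc <- assess_pvalues(assoc, inputs, index, cfg$n_permutations, cfg$seed,
                          cfg$shared_sets)
  assoc$passed_chemicals <- assoc$pvalue_chemicals <= thresholds[["chemicals"]]
  assoc$passed_genes <- assoc$pvalue_genes <= thresholds[["genes"]]
  report$assessments <- assoc
  passed <- apply_thresholds(assoc, thresholds)
  report$counts["permutation"] <- nrow(passed)
  stage_msg("permutation test: ", nrow(passed), " compounds")
  if (!nrow(passed)) return(report)

  refined <- iterative_refine(passed$compound, inputs, index,
                              rounds = cfg$rounds, folds = cfg$folds,
                              k_max = cfg$k_max, policy = cfg$policy,
                              seed = cfg$seed, tol = cfg$tol,
                              max_iter = cfg$max_iter)
  report$audit <- refined$audit
  for (r in seq_len(nrow(refined$audit))) {
    report$counts[paste0("cluster_round_", r)] <- refined$audit$n_survivors[r]
  }
  putative <- passed[passed$compound %in% refined$candidates, , drop = FALSE]
  putative$linked_genes <- vapply(
    putative$compound,
    function(c) paste(.linked_genes(c, inputs$gene_map, index), collapse = ","),
    character(1)
  )
  rownames(putative) <- NULL
  report$putative <- putative
  report$counts["putative"] <- nrow(putative)
  stage_msg("putative compounds: ", nrow(putative))

  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Three-step candidate screen (seed ", x$seed, ")\n", sep = "")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-16s %d\n", nm, x$counts[[nm]]))
  }
  if (!is.null(x$thresholds)) {
    cat(sprintf("  P-value thresholds: chemicals <= %.3f, genes <= %.3f\n",
                x$thresholds[["chemicals"]], x$thresholds[["genes"]]))
  }
  invisible(x)
}

#' @export
summary.screen_report <- function(object, ...) {
  print(object)
  if (!is.null(object$putative) && nrow(object$putative)) {
    cat("\nPutative compounds:\n")
    print(object$putative, row.names = FALSE)
  }
  invisible(object)
}

#' Write the stage outputs of a screening run as TSV
#'
#' Emits `assessments.tsv`, `drug_assessments.tsv`, `putative.tsv` and
#' `cluster_audit.tsv` (those available), each with a commented header
#' recording the package version and run seed.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(
    paste0("# chemscreen ", as.character(utils::packageVersion("chemscreen"))),
    paste0("# seed=", report$seed),
    if (!is.null(report$thresholds))
      paste0("# thresholds chemicals=", report$thresholds[["chemicals"]],
             " genes=", report$thresholds[["genes"]])
  )
  emit <- function(df, name) {
    if (is.null(df)) return()
    path <- file.path(dir, name)
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
  }
  emit(report$assessments, "assessments.tsv")
  emit(report$drug_assessments, "drug_assessments.tsv")
  emit(report$putative, "putative.tsv")
  emit(report$audit, "cluster_audit.tsv")
  counts <- data.frame(stage = names(report$counts),
                       count = as.integer(report$counts))
  emit(counts, "stage_counts.tsv")
  invisible(dir)
}

#' Export the putative-compound subnetwork
#'
#' Collects every positive-combined interaction among the putative
#' compounds, the approved drugs and the disease genes' proteins: the
#' chemical-chemical links among the compounds and the protein-chemical
#' links from those compounds to the disease proteins, each weighted by its
#' combined score.
#'
#' @param report A [run_pipeline()] result (or any object with a
#'   `putative$compound` column).
#' @param inputs A [screen_inputs()] object.
#' @param index A [build_index()] result.
#' @return An object of class `"subnetwork"`: `edges` (data frame `source`,
#'   `target`, `edge_type`, `combined`) and `nodes` (data frame `id`,
#'   `node_type` with types `putative`, `drug`, `disease_protein`).
#' @export
export_subnetwork <- function(report, inputs = report$inputs,
                              index = report$index) {
  putative <- if (is.null(report$putative)) integer(0) else report$putative$compound
  node_chems <- sort(unique(c(putative, inputs$drugs)))
  edges <- list()
  for (c in node_chems) {
    nb <- chem_neighbors(index, c)
    nb <- nb[nb$neighbor %in% node_chems & nb$neighbor > c, , drop = FALSE]
    if (nrow(nb)) {
      edges[[length(edges) + 1L]] <- data.frame(
        source = as.character(c), target = as.character(nb$neighbor),
        edge_type = "chemical-chemical", combined = nb$combined
      )
    }
    pp <- protein_partners(index, c)
    pp <- pp[pp$protein %in% inputs$disease_proteins, , drop = FALSE]
    if (nrow(pp)) {
      edges[[length(edges) + 1L]] <- data.frame(
        source = as.character(c), target = pp$protein,
        edge_type = "protein-chemical", combined = pp$combined
      )
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(0), target = character(0),
               edge_type = character(0), combined = integer(0))
  nodes <- data.frame(
    id = c(as.character(putative), as.character(inputs$drugs),
           inputs$disease_proteins),
    node_type = c(rep("putative", length(putative)),
                  rep("drug", length(inputs$drugs)),
                  rep("disease_protein", length(inputs$disease_proteins)))
  )
  structure(list(edges = edges, nodes = nodes), class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("Subnetwork:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Write a subnetwork as weighted edge-list and node-annotation TSVs
#'
#' @param network An [export_subnetwork()] result.
#' @param path Edge-list output path; node annotations go to
#'   `<path>.nodes.tsv`.
#' @return `path`, invisibly.
#' @export
write_subnetwork <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(network$nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
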