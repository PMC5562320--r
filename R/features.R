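# The 15-dimensional interaction-score encoding used for co-clustering:
# five chemical channels against the approved drugs, five against the
# disease chemicals, and five protein channels against the disease genes.
# Each feature is the mean of that channel over the partners with a
# strictly positive score on that channel, and 0 when no such partner
# exists (per-channel support).

# Mean of each score column over rows with a strictly positive entry in
# that column; 0 for empty support.
.channel_means <- function(df, cols) {
  vapply(cols, function(cl) {
    v <- df[[cl]]
    v <- v[v > 0]
    if (length(v)) mean(v) else 0
  }, numeric(1))
}

#' Encode a compound as its 15 mean-interaction-score features
#'
#' Features 1-5: mean similarity / experimental / database / textmining /
#' combined score of the chemical links between the compound and the
#' approved drugs. Features 6-10: the same five channels against the
#' disease-related chemicals. Features 11-15: mean experimental /
#' prediction / database / textmining / combined score of the protein
#' links between the compound and the disease-related genes' proteins.
#' Each mean runs over the partners with a strictly positive score on that
#' channel and is 0 when there is none.
#'
#' @param c Compound id.
#' @param inputs A [screen_inputs()] object.
#' @param index A [build_index()] result.
#' @return Named numeric vector of length 15, entries in `[0, 1000]`.
#' @export
encode_features <- function(c, inputs, index) {
  nb <- chem_neighbors(index, c)
  vs_drugs <- nb[nb$neighbor %in% inputs$drugs, , drop = FALSE]
  vs_chems <- nb[nb$neighbor %in% inputs$disease_chemicals, , drop = FALSE]
  vs_genes <- gene_partner_links(c, inputs$gene_map, index)
  out <- c(.channel_means(vs_drugs, .CHEM_SCORE_COLS),
           .channel_means(vs_chems, .CHEM_SCORE_COLS),
           .channel_means(vs_genes, .PROT_SCORE_COLS))
  names(out) <- .FEATURE_NAMES
  out
}

#' Encode a cohort of candidates plus the approved drugs
#'
#' Stacks [encode_features()] rows for the candidate compounds and the
#' drugs (the drugs are encoded with the same 15 features). Row order is
#' deterministic: sorted by compound id.
#'
#' @param compounds Integer vector of candidate compound ids.
#' @param inputs A [screen_inputs()] object (supplies the drug set).
#' @param index A [build_index()] result.
#' @return A list with `features` (numeric matrix, one row per compound,
#'   rownames the compound ids) and `is_drug` (logical vector aligned to
#'   the rows).
#' @export
encode_cohort <- function(compounds, inputs, index) {
  compounds <- setdiff(as.integer(compounds), inputs$drugs)
  all_ids <- sort(unique(c(compounds, inputs$drugs)))
  feats <- t(vapply(all_ids, encode_features, numeric(15),
                    inputs = inputs, index = index))
  rownames(feats) <- as.character(all_ids)
  colnames(feats) <- .FEATURE_NAMES
  list(features = feats, is_drug = all_ids %in% inputs$drugs)
}

#' Write a feature matrix as TSV
#'
#' @param cohort An [encode_cohort()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(cohort, path) {
  df <- data.frame(compound = rownames(cohort$features),
                   is_drug = as.integer(cohort$is_drug),
                   cohort$features, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
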