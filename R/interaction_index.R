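# Neighbor indexes over the parsed link tables. Lookups are plain
# environment hash maps keyed by the character form of the compound id, so
# screening and permutation scoring avoid repeated table scans.

#' Build a neighbor index over parsed interaction tables
#'
#' Indexes every positive-combined link for O(1) neighbor lookups:
#' chemical neighbors are symmetric (each undirected link is stored under
#' both endpoints), protein partners are stored under the chemical.
#'
#' @param tables An [interaction_tables()] object.
#' @return An object of class `"neighbor_index"` with environments
#'   `chem_adj` (cid -> data frame of neighbor + five chemical channels)
#'   and `prot_adj` (cid -> data frame of protein + five protein channels),
#'   plus `chemical_universe` and `protein_universe` vectors.
#' @export
build_index <- function(tables) {
  stopifnot(inherits(tables, "interaction_tables"))
  cl <- tables$chemical_links
  cl <- cl[cl$combined > 0, , drop = FALSE]
  chem_adj <- new.env(parent = emptyenv(), size = max(2L * nrow(cl), 29L))
  if (nrow(cl)) {
    both <- rbind(
      data.frame(self = cl$chem_a, neighbor = cl$chem_b,
                 cl[, .CHEM_SCORE_COLS], stringsAsFactors = FALSE),
      data.frame(self = cl$chem_b, neighbor = cl$chem_a,
                 cl[, .CHEM_SCORE_COLS], stringsAsFactors = FALSE)
    )
    parts <- split(both[-1L], both$self)
    for (nm in names(parts)) assign(nm, parts[[nm]], envir = chem_adj)
  }
  pl <- tables$protein_links
  pl <- pl[pl$combined > 0, , drop = FALSE]
  prot_adj <- new.env(parent = emptyenv(), size = max(nrow(pl), 29L))
  if (nrow(pl)) {
    pparts <- split(pl[, c("protein", .PROT_SCORE_COLS)], pl$chemical)
    for (nm in names(pparts)) assign(nm, pparts[[nm]], envir = prot_adj)
  }
  structure(
    list(
      chem_adj = chem_adj,
      prot_adj = prot_adj,
      chemical_universe = tables$chemical_universe,
      protein_universe = sort(unique(pl$protein))
    ),
    class = "neighbor_index"
  )
}

#' @export
print.neighbor_index <- function(x, ...) {
  cat("Neighbor index:", length(x$chemical_universe), "compounds,",
      length(x$protein_universe), "proteins\n")
  invisible(x)
}

# Chemical neighbors of a compound (data frame, possibly 0-row).
chem_neighbors <- function(index, c) {
  key <- as.character(c)
  if (exists(key, envir = index$chem_adj, inherits = FALSE)) {
    get(key, envir = index$chem_adj, inherits = FALSE)
  } else {
    data.frame(neighbor = integer(0), similarity = integer(0),
               experimental = integer(0), database = integer(0),
               textmining = integer(0), combined = integer(0))
  }
}

# Protein partners of a compound (data frame, possibly 0-row).
protein_partners <- function(index, c) {
  key <- as.character(c)
  if (exists(key, envir = index$prot_adj, inherits = FALSE)) {
    get(key, envir = index$prot_adj, inherits = FALSE)
  } else {
    data.frame(protein = character(0), experimental = integer(0),
               prediction = integer(0), database = integer(0),
               textmining = integer(0), combined = integer(0))
  }
}

#' Assemble the screening inputs
#'
#' @param drugs Integer vector of approved-drug CIDs.
#' @param disease_chemicals Integer vector of disease-related chemical CIDs.
#' @param gene_map Named list mapping gene symbols to character vectors of
#'   protein identifiers (see [read_gene_map()]).
#' @return An object of class `"screen_inputs"`; `disease_proteins` is the
#'   deduplicated union of all mapped protein identifiers.
#' @export
screen_inputs <- function(drugs, disease_chemicals, gene_map) {
  if (!length(drugs)) stop("empty drug set", call. = FALSE)
  if (!length(disease_chemicals)) stop("empty disease-chemical set", call. = FALSE)
  if (!length(gene_map)) stop("empty disease-gene set", call. = FALSE)
  structure(
    list(
      drugs = sort(unique(as.integer(drugs))),
      disease_chemicals = sort(unique(as.integer(disease_chemicals))),
      gene_map = gene_map,
      disease_proteins = sort(unique(unlist(gene_map, use.names = FALSE)))
    ),
    class = "screen_inputs"
  )
}

#' @export
print.screen_inputs <- function(x, ...) {
  cat("Screen inputs:", length(x$drugs), "drugs,",
      length(x$disease_chemicals), "disease chemicals,",
      length(x$gene_map), "disease genes (",
      length(x$disease_proteins), "proteins )\n")
  invisible(x)
}

#' Protein-chemical links between a compound and a disease gene set
#'
#' Returns the links from compound `c` to any protein mapped by any gene in
#' `gene_map`. A gene with several protein identifiers contributes each
#' linked protein once; genes sharing a protein do not duplicate the link
#' (set semantics over proteins).
#'
#' @param c Compound id.
#' @param gene_map Named list of gene -> protein ids.
#' @param index A [build_index()] result.
#' @return Data frame of protein links (possibly 0-row).
#' @export
gene_partner_links <- function(c, gene_map, index) {
  pp <- protein_partners(index, c)
  targets <- unique(unlist(gene_map, use.names = FALSE))
  pp[pp$protein %in% targets, , drop = FALSE]
}
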