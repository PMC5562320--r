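# Readers and writers for the STITCH "detailed links" TSV dialects.
#
# Chemical-chemical links carry five evidence scores (similarity,
# experimental, database, textmining, combined_score); protein-chemical
# links carry experimental, prediction, database, textmining,
# combined_score. All scores are integers on the 0-1000 STITCH scale.
# Link existence throughout the package means combined_score > 0.

#' Normalize a STITCH/PubChem compound identifier to an integer CID
#'
#' STITCH encodes PubChem compound identifiers as `"CIDm<digits>"` (merged
#' stereo-isomers) or `"CIDs<digits>"` (stereo-specific), zero-padded to
#' eight digits; plain `"CID<digits>"` and bare digit strings are also
#' accepted. All flavors of the same compound map to the same integer CID.
#'
#' @param raw_id Character vector of identifiers, e.g. `"CIDm00004033"`,
#'   `"CID4033"`, `"4033"`.
#' @param flatten_stereo If `FALSE`, the returned vector carries a
#'   `"flavor"` attribute (`"merged"`, `"stereo"` or `"plain"` per element)
#'   so callers can distinguish the record flavor; the integer values are
#'   identical either way.
#' @return Integer vector of PubChem CIDs.
#' @examples
#' normalize_cid("CIDm00004033")  # 4033
#' normalize_cid(c("CID4033", "123"))
#' @export
normalize_cid <- function(raw_id, flatten_stereo = TRUE) {
  raw_id <- as.character(raw_id)
  m <- regmatches(raw_id, regexec("^CID([ms]?)([0-9]+)$", raw_id))
  bare <- grepl("^[0-9]+$", raw_id)
  ok <- bare | lengths(m) == 3L
  if (any(!ok)) {
    stop("malformed compound identifier: ", paste(unique(raw_id[!ok]), collapse = ", "),
         call. = FALSE)
  }
  digits <- ifelse(bare, raw_id, vapply(m, function(x) if (length(x) == 3L) x[3L] else NA_character_,
                                        character(1)))
  cid <- suppressWarnings(as.integer(digits))
  if (anyNA(cid)) {
    stop("compound identifier out of integer range: ",
         paste(unique(raw_id[is.na(cid)]), collapse = ", "), call. = FALSE)
  }
  if (any(cid <= 0L)) {
    stop("compound identifier must be a positive integer: ",
         paste(unique(raw_id[cid <= 0L]), collapse = ", "), call. = FALSE)
  }
  if (!flatten_stereo) {
    flavor <- ifelse(bare, "plain",
                     vapply(m, function(x) switch(x[2L], m = "merged", s = "stereo", "plain"),
                            character(1)))
    attr(cid, "flavor") <- flavor
  }
  cid
}

# Read a TSV (optionally gzip) and check the required columns are present.
.read_links_tsv <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, ": missing column(s) ", paste(missing, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  df
}

# Validate integer scores in [0, 1000]; report 1-based data line numbers
# (header is line 1).
.check_scores <- function(df, cols, path) {
  for (cl in cols) {
    v <- df[[cl]]
    if (is.character(v)) {
      vi <- suppressWarnings(as.integer(v))
      bad <- which(is.na(vi) | vi != suppressWarnings(as.numeric(v)))
      if (length(bad)) {
        stop("non-integer score in column '", cl, "' at line ", bad[1L] + 1L,
             " of ", path, call. = FALSE)
      }
      v <- vi
    } else if (is.double(v)) {
      bad <- which(is.na(v) | v != round(v))
      if (length(bad)) {
        stop("non-integer score in column '", cl, "' at line ", bad[1L] + 1L,
             " of ", path, call. = FALSE)
      }
      v <- as.integer(v)
    }
    bad <- which(is.na(v) | v < 0L | v > 1000L)
    if (length(bad)) {
      stop("score out of [0, 1000] in column '", cl, "' at line ", bad[1L] + 1L,
           " of ", path, call. = FALSE)
    }
    df[[cl]] <- v
  }
  df
}

# Collapse duplicate keys: identical score rows merge silently; conflicting
# rows keep the larger combined score with a warning (maximal evidence).
.dedup_links <- function(df, key, score_cols, what) {
  if (!anyDuplicated(key)) return(df)
  ord <- order(key, -df$combined)
  df <- df[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  dup_rows <- df[!first, score_cols, drop = FALSE]
  kept_rows <- df[first, , drop = FALSE][match(key[!first], key[first]), score_cols, drop = FALSE]
  conflict <- rowSums(dup_rows != kept_rows) > 0
  if (any(conflict)) {
    warning(sum(conflict), " duplicate ", what,
            " pair(s) with conflicting scores; kept the larger combined score",
            call. = FALSE)
  }
  df[first, , drop = FALSE]
}

#' Read a chemical-chemical links table
#'
#' Parses the STITCH `chemical_chemical.links.detailed` dialect: a TSV
#' (plain or gzip) with columns `chemical_a`, `chemical_b`, `similarity`,
#' `experimental`, `database`, `textmining`, `combined_score`. Links are
#' undirected: duplicate orientations of the same pair are merged (scores
#' must agree; on conflict the record with the larger combined score wins,
#' with a warning). Records with `combined_score <= min_combined` are
#' dropped, so with the default only interacting pairs are retained.
#'
#' @param path Path to the TSV file.
#' @param min_combined Drop records whose combined score is less than or
#'   equal to this value (default 0, the interaction-existence rule).
#' @return A data frame with integer columns `chem_a`, `chem_b` (canonical
#'   order `chem_a < chem_b`), `similarity`, `experimental`, `database`,
#'   `textmining`, `combined`.
#' @seealso [read_protein_links()], [interaction_tables()]
#' @export
read_chemical_links <- function(path, min_combined = 0) {
  req <- c("chemical_a", "chemical_b", "similarity", "experimental",
           "database", "textmining", "combined_score")
  df <- .read_links_tsv(path, req, "chemical links")
  out <- data.frame(
    chem_a = normalize_cid(df$chemical_a),
    chem_b = normalize_cid(df$chemical_b),
    df[, c("similarity", "experimental", "database", "textmining")],
    combined = df$combined_score,
    stringsAsFactors = FALSE
  )
  out <- .check_scores(out, .CHEM_SCORE_COLS, path)
  if (any(out$chem_a == out$chem_b)) {
    stop("self-interaction at line ",
         which(out$chem_a == out$chem_b)[1L] + 1L, " of ", path, call. = FALSE)
  }
  # canonical unordered orientation
  swap <- out$chem_a > out$chem_b
  if (any(swap)) {
    tmp <- out$chem_a[swap]
    out$chem_a[swap] <- out$chem_b[swap]
    out$chem_b[swap] <- tmp
  }
  key <- paste(out$chem_a, out$chem_b, sep = "_")
  out <- .dedup_links(out, key, .CHEM_SCORE_COLS, "chemical")
  out <- out[out$combined > min_combined, , drop = FALSE]
  out <- out[order(out$chem_a, out$chem_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a protein-chemical links table
#'
#' Parses the STITCH `protein_chemical.links.detailed` dialect: a TSV with
#' columns `protein` (organism-prefixed identifier such as
#' `"9606.ENSP00000354587"`), `chemical`, `experimental`, `prediction`,
#' `database`, `textmining`, `combined_score`. Only records whose organism
#' prefix equals `organism` are retained; the prefix is stripped from the
#' stored protein identifier. Records with `combined_score <= min_combined`
#' are dropped.
#'
#' @param path Path to the TSV file.
#' @param organism Organism code to retain (default `"9606"`, human).
#' @param min_combined Combined-score cutoff (default 0).
#' @return A data frame with columns `protein` (character), `chemical`
#'   (integer CID), `experimental`, `prediction`, `database`, `textmining`,
#'   `combined`.
#' @export
read_protein_links <- function(path, organism = "9606", min_combined = 0) {
  req <- c("protein", "chemical", "experimental", "prediction",
           "database", "textmining", "combined_score")
  df <- .read_links_tsv(path, req, "protein links")
  prot <- as.character(df$protein)
  dot <- regexpr(".", prot, fixed = TRUE)
  if (any(dot < 0L)) {
    stop("protein identifier without organism prefix at line ",
         which(dot < 0L)[1L] + 1L, " of ", path, call. = FALSE)
  }
  org <- substr(prot, 1L, dot - 1L)
  keep <- org == organism
  df <- df[keep, , drop = FALSE]
  prot <- substring(prot[keep], dot[keep] + 1L)
  out <- data.frame(
    protein = prot,
    chemical = if (nrow(df)) normalize_cid(df$chemical) else integer(0),
    df[, c("experimental", "prediction", "database", "textmining")],
    combined = df$combined_score,
    stringsAsFactors = FALSE
  )
  out <- .check_scores(out, .PROT_SCORE_COLS, path)
  key <- paste(out$protein, out$chemical, sep = "_")
  out <- .dedup_links(out, key, .PROT_SCORE_COLS, "protein-chemical")
  out <- out[out$combined > min_combined, , drop = FALSE]
  out <- out[order(out$protein, out$chemical), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write links tables back to the STITCH dialect
#'
#' Inverse of [read_chemical_links()] / [read_protein_links()]; useful for
#' round-tripping and for exporting filtered tables. Compound identifiers
#' are written in the `CIDm<8 digits>` form; protein identifiers get the
#' organism prefix back.
#'
#' @param links A parsed links data frame.
#' @param path Output path (plain TSV).
#' @param organism Organism prefix to restore (protein links only).
#' @return `path`, invisibly.
#' @export
write_chemical_links <- function(links, path) {
  df <- data.frame(
    chemical_a = sprintf("CIDm%08d", links$chem_a),
    chemical_b = sprintf("CIDm%08d", links$chem_b),
    links[, c("similarity", "experimental", "database", "textmining")],
    combined_score = links$combined
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chemical_links
#' @export
write_protein_links <- function(links, path, organism = "9606") {
  df <- data.frame(
    protein = paste(organism, links$protein, sep = "."),
    chemical = sprintf("CIDm%08d", links$chemical),
    links[, c("experimental", "prediction", "database", "textmining")],
    combined_score = links$combined
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundle parsed link tables
#'
#' @param chemical_links Data frame from [read_chemical_links()].
#' @param protein_links Data frame from [read_protein_links()].
#' @return An object of class `"interaction_tables"` with elements
#'   `chemical_links`, `protein_links` and `chemical_universe` (sorted
#'   integer vector of every compound appearing in a chemical link).
#' @export
interaction_tables <- function(chemical_links, protein_links) {
  structure(
    list(
      chemical_links = chemical_links,
      protein_links = protein_links,
      chemical_universe = sort(unique(c(chemical_links$chem_a, chemical_links$chem_b)))
    ),
    class = "interaction_tables"
  )
}

#' @export
print.interaction_tables <- function(x, ...) {
  cat("Interaction tables:", nrow(x$chemical_links), "chemical-chemical links,",
      nrow(x$protein_links), "protein-chemical links,",
      length(x$chemical_universe), "compounds\n")
  invisible(x)
}

#' Read a compound list (one identifier per line, '#' comments allowed)
#'
#' @param path Path to the list file.
#' @return Sorted integer vector of CIDs.
#' @export
read_compound_list <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sort(unique(normalize_cid(lines)))
}

#' Read a gene-to-protein mapping
#'
#' Two-column TSV `gene` / `protein` (header required), one row per
#' mapping; a gene may map to several protein identifiers. Protein
#' identifiers must already be organism-stripped (matching the identifiers
#' stored by [read_protein_links()]).
#'
#' @param path Path to the TSV.
#' @return A named list: one character vector of protein ids per gene
#'   symbol.
#' @export
read_gene_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("gene", "protein") %in% names(df))) {
    stop("gene map must have columns 'gene' and 'protein'", call. = FALSE)
  }
  lapply(split(as.character(df$protein), as.character(df$gene)), unique)
}
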