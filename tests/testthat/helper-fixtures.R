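# In-code fixtures and independent linear-scan oracles. The oracles work
# directly on the raw link data frames (both orientations scanned), never
# through the package's index structures.

# ---- file writers -----------------------------------------------------------

h_write_chem <- function(rows, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(chemical_a = rows$chemical_a, chemical_b = rows$chemical_b,
                   similarity = rows$similarity, experimental = rows$experimental,
                   database = rows$database, textmining = rows$textmining,
                   combined_score = rows$combined_score)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

h_write_prot <- function(rows, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(protein = rows$protein, chemical = rows$chemical,
                   experimental = rows$experimental, prediction = rows$prediction,
                   database = rows$database, textmining = rows$textmining,
                   combined_score = rows$combined_score)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

h_chem_row <- function(a, b, combined, similarity = 0, experimental = 0,
                       database = 0, textmining = 0) {
  data.frame(chemical_a = sprintf("CID%d", a), chemical_b = sprintf("CID%d", b),
             similarity = similarity, experimental = experimental,
             database = database, textmining = textmining,
             combined_score = combined)
}

# ---- random small worlds ----------------------------------------------------

# Random chemical + protein link tables over n_compounds compounds and
# n_proteins proteins; returns parsed-style frames plus file paths.
h_random_tables <- function(seed, n_compounds = 50, n_proteins = 12,
                            n_chem_links = 120, n_prot_links = 60) {
  set.seed(seed)
  ids <- seq_len(n_compounds) + 100L
  pairs <- t(combn(ids, 2))
  pick <- sample(nrow(pairs), min(n_chem_links, nrow(pairs)))
  chem <- data.frame(
    chemical_a = sprintf("CIDm%08d", pairs[pick, 1]),
    chemical_b = sprintf("CIDm%08d", pairs[pick, 2]),
    similarity = sample(0:1000, length(pick), TRUE),
    experimental = sample(0:1000, length(pick), TRUE),
    database = sample(0:1000, length(pick), TRUE),
    textmining = sample(0:1000, length(pick), TRUE),
    combined_score = sample(0:1000, length(pick), TRUE)
  )
  prots <- sprintf("ENSP%07d", seq_len(n_proteins))
  pc <- expand.grid(protein = prots, chemical = ids, stringsAsFactors = FALSE)
  pc <- pc[sample(nrow(pc), min(n_prot_links, nrow(pc))), ]
  prot <- data.frame(
    protein = paste0("9606.", pc$protein),
    chemical = sprintf("CIDm%08d", pc$chemical),
    experimental = sample(0:1000, nrow(pc), TRUE),
    prediction = sample(0:1000, nrow(pc), TRUE),
    database = sample(0:1000, nrow(pc), TRUE),
    textmining = sample(0:1000, nrow(pc), TRUE),
    combined_score = sample(0:1000, nrow(pc), TRUE)
  )
  list(
    ids = ids, proteins = prots,
    chem_path = h_write_chem(chem), prot_path = h_write_prot(prot),
    chem_raw = chem, prot_raw = prot
  )
}

h_tables_from_paths <- function(w) {
  interaction_tables(read_chemical_links(w$chem_path),
                     read_protein_links(w$prot_path))
}

# ---- linear-scan oracles (independent of the index) -------------------------

# raw chem frame in parsed form: integer chem_a/chem_b + channel columns
h_parse_raw_chem <- function(chem_raw) {
  data.frame(
    chem_a = as.integer(sub("CIDm0*", "", chem_raw$chemical_a)),
    chem_b = as.integer(sub("CIDm0*", "", chem_raw$chemical_b)),
    similarity = chem_raw$similarity, experimental = chem_raw$experimental,
    database = chem_raw$database, textmining = chem_raw$textmining,
    combined = chem_raw$combined_score
  )
}

h_parse_raw_prot <- function(prot_raw) {
  keep <- startsWith(prot_raw$protein, "9606.")
  data.frame(
    protein = sub("^9606\\.", "", prot_raw$protein[keep]),
    chemical = as.integer(sub("CIDm0*", "", prot_raw$chemical[keep])),
    experimental = prot_raw$experimental[keep],
    prediction = prot_raw$prediction[keep],
    database = prot_raw$database[keep],
    textmining = prot_raw$textmining[keep],
    combined = prot_raw$combined_score[keep]
  )
}

# all chemical links of c with combined > 0, scanning both orientations
bf_chem_links <- function(chem, c) {
  hit <- (chem$chem_a == c | chem$chem_b == c) & chem$combined > 0
  out <- chem[hit, , drop = FALSE]
  out$partner <- ifelse(out$chem_a == c, out$chem_b, out$chem_a)
  out
}

bf_prot_links <- function(prot, c) {
  prot[prot$chemical == c & prot$combined > 0, , drop = FALSE]
}

bf_preliminary <- function(chem, drugs) {
  hits <- unlist(lapply(drugs, function(d) bf_chem_links(chem, d)$partner))
  sort(setdiff(unique(hits), drugs))
}

bf_rs_chem <- function(chem, c, reference) {
  ln <- bf_chem_links(chem, c)
  sc <- ln$combined[ln$partner %in% reference]
  if (length(sc)) mean(sc) else 0
}

bf_rs_gene <- function(prot, c, proteins) {
  ln <- bf_prot_links(prot, c)
  sc <- ln$combined[ln$protein %in% proteins]
  if (length(sc)) mean(sc) else 0
}

# 15-feature encoding by direct scan with per-channel positive support
bf_encode <- function(chem, prot, c, drugs, disease_chems, disease_proteins) {
  chan_mean <- function(v) if (any(v > 0)) mean(v[v > 0]) else 0
  cl <- bf_chem_links(chem, c)
  vs_drug <- cl[cl$partner %in% drugs, , drop = FALSE]
  vs_chem <- cl[cl$partner %in% disease_chems, , drop = FALSE]
  pl <- bf_prot_links(prot, c)
  pl <- pl[pl$protein %in% disease_proteins, , drop = FALSE]
  c(vapply(c("similarity", "experimental", "database", "textmining", "combined"),
           function(ch) chan_mean(vs_drug[[ch]]), numeric(1)),
    vapply(c("similarity", "experimental", "database", "textmining", "combined"),
           function(ch) chan_mean(vs_chem[[ch]]), numeric(1)),
    vapply(c("experimental", "prediction", "database", "textmining", "combined"),
           function(ch) chan_mean(pl[[ch]]), numeric(1)))
}

# ---- misc -------------------------------------------------------------------

# inputs/index over a tiny explicit link set given as parsed-style frames
h_mini_world <- function(chem_rows, prot_rows = NULL) {
  chem_path <- h_write_chem(chem_rows)
  if (is.null(prot_rows)) {
    prot_rows <- data.frame(protein = "9606.ENSP0000001", chemical = "CID999999",
                            experimental = 0, prediction = 0, database = 0,
                            textmining = 0, combined_score = 500)
  }
  prot_path <- h_write_prot(prot_rows)
  tables <- interaction_tables(read_chemical_links(chem_path),
                               read_protein_links(prot_path))
  list(tables = tables, index = build_index(tables))
}
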