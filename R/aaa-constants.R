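# Shared column and feature-name constants (loaded before the other files).

# STITCH evidence channels, chemical-chemical and protein-chemical tables.
.CHEM_SCORE_COLS <- c("similarity", "experimental", "database", "textmining", "combined")
.PROT_SCORE_COLS <- c("experimental", "prediction", "database", "textmining", "combined")

# Order of the 15-dimensional feature encoding: five chemical channels
# against the approved drugs, five against the disease chemicals, five
# protein channels against the disease genes.
.FEATURE_NAMES <- c(
  paste0("drug_", .CHEM_SCORE_COLS),
  paste0("chem_", .CHEM_SCORE_COLS),
  paste0("gene_", .PROT_SCORE_COLS)
)
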