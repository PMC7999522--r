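# Fixture builders shared across test files. Everything is generated in code;
# no fixture files ship with the package.

fixture_metadata <- function(run_id = "run1", construct = "bait_fusion",
                             cell_line = "HCT116", biotin_hours = 6,
                             treatment = "vehicle", replicate = 1,
                             batch_id = "batchA") {
  run_metadata(run_id, cell_line, construct, biotin_hours, treatment,
               replicate, batch_id)
}

# random valid evidence table honouring the invariants
# (unique accessions, non-negative counts, zero peptides => zero abundance)
random_evidence <- function(n = 20, metadata = fixture_metadata(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  peptides <- rpois(n, 6)
  abundance <- ifelse(peptides == 0, 0, round(rlnorm(n, 13, 1), 4))
  evidence_table(
    data.frame(
      accession = sprintf("ACC%04d", sample.int(9999, n)),
      gene = sprintf("GENE%d", seq_len(n)),
      unique_peptides = peptides,
      abundance = abundance,
      stringsAsFactors = FALSE
    ),
    metadata
  )
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a hand-built ratio table with full control over peptide counts and ratios
make_ratio_table <- function(gene, ratio, bait_peptides, control_peptides,
                             batch_id = "HCT116_6h_vehicle",
                             treatment = "vehicle") {
  structure(data.frame(
    accession = paste0("ACC_", gene), gene = gene,
    cell_line = "HCT116", biotin_hours = 6, treatment = treatment,
    batch_id = batch_id, ratio = ratio, ratio_defined = !is.na(ratio),
    bait_peptides = bait_peptides, control_peptides = control_peptides,
    stringsAsFactors = FALSE
  ), class = c("ratio_table", "data.frame"))
}

# six-protein truth table exercising every cascade removal stage:
#   PASS1  passes everything
#   LOWPEP bait peptides exactly at the floor (3): strict "more than" fails
#   NOCTRL control peptides 0: control-evidence floor fails
#   REVDIR control peptides exceed bait peptides: direction filter fails
#   KRT18  keratin exclusion
#   PCCA   endogenous-biotin exclusion
#   LOWRAT ratio exactly at the threshold (1.5): strict "higher than" fails
cascade_truth_fixture <- function() {
  make_ratio_table(
    gene            = c("PASS1", "LOWPEP", "NOCTRL", "REVDIR", "KRT18", "PCCA", "LOWRAT"),
    ratio           = c(2.0,     2.0,      2.0,      2.0,      2.0,     2.0,    1.5),
    bait_peptides   = c(4L,      3L,       10L,      4L,       6L,      6L,     6L),
    control_peptides= c(1L,      5L,       0L,       5L,       2L,      2L,     2L)
  )
}
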