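test_that("evidence tables round-trip through disk and validate on read", {
  md <- fixture_metadata()
  tab <- data.frame(accession = c("P1", "P2", "P3"), gene = c("A", "B", "C"),
                    unique_peptides = c(5L, 2L, 1L), abundance = c(1e6, 2e5, 3e3))
  path <- write_tsv_fixture(tab)
  ev <- read_evidence(path, md)
  expect_s3_class(ev, "evidence_table")
  expect_equal(nrow(ev), 3)
  expect_equal(ev$accession, tab$accession)  # row order preserved

  # write-then-read is the identity on random valid tables
  set.seed(42)
  for (i in 1:10) {
    ev <- random_evidence(n = sample(5:40, 1), metadata = md)
    p <- tempfile(fileext = sample(c(".tsv", ".csv"), 1))
    write_evidence(ev, p)
    back <- read_evidence(p, md)
    expect_equal(as.data.frame(back), as.data.frame(ev))
  }
})

test_that("evidence validation rejects malformed rows with row numbers", {
  md <- fixture_metadata()
  bad_count <- write_tsv_fixture(data.frame(
    accession = "P1", gene = "A", unique_peptides = -1L, abundance = 10))
  expect_error(read_evidence(bad_count, md), "row 1",
               class = "bioid_validation_error")
  dup <- write_tsv_fixture(data.frame(
    accession = c("P1", "P1"), gene = c("A", "B"),
    unique_peptides = c(2L, 3L), abundance = c(1, 2)))
  expect_error(read_evidence(dup, md), "duplicate accession",
               class = "bioid_validation_error")
  no_col <- write_tsv_fixture(data.frame(accession = "P1", gene = "A",
                                         unique_peptides = 1L))
  expect_error(read_evidence(no_col, md), "abundance",
               class = "bioid_format_error")
  ghost <- write_tsv_fixture(data.frame(
    accession = "P1", gene = "A", unique_peptides = 0L, abundance = 10))
  expect_error(read_evidence(ghost, md), class = "bioid_validation_error")
})

test_that("header aliases and delimiter detection work", {
  md <- fixture_metadata()
  tab <- data.frame(Protein = "P1", Symbol = "A", Peptides = 4L, Intensity = 100)
  p <- tempfile(fileext = ".csv")
  write.csv(tab, p, row.names = FALSE, quote = FALSE)
  ev <- read_evidence(p, md)
  expect_equal(ev$gene, "A")
  expect_equal(ev$abundance, 100)
})

test_that("annotation readers collapse duplicates and build the background", {
  pairs <- c("term_id\tgene", "T1\tg1", "T1\tg2", "T2\tg2", "T2\tg2")
  p <- tempfile(fileext = ".tsv"); writeLines(pairs, p)
  ann <- read_annotations(p, format = "two_column_tsv")
  expect_equal(lengths(ann$term_to_genes)[c("T1", "T2")], c(T1 = 2L, T2 = 1L))
  expect_equal(ann$background, c("G1", "G2"))  # duplicate pair counted once

  gaf <- c("!gaf-version: 2.1",
           paste("DB", "ID1", "g1", "", "GO:1", "REF", "IEA", "", "P", sep = "\t"),
           paste("DB", "ID2", "g2", "", "GO:1", "REF", "IEA", "", "C", sep = "\t"),
           paste("DB", "ID3", "g3", "", "GO:2", "REF", "IEA", "", "F", sep = "\t"),
           paste("DB", "ID4", "g4", "", "GO:2", "REF", "IEA", "", "P", sep = "\t"))
  pg <- tempfile(); writeLines(gaf, pg)
  ann2 <- read_annotations(pg, format = "gaf_like")
  expect_equal(sum(lengths(ann2$term_to_genes)), 4L)
  expect_setequal(ann2$term_meta$term_id, c("GO:1", "GO:2"))

  bad <- sub("\tP$", "\tX", gaf[2]); pb <- tempfile(); writeLines(c(gaf[1], bad), pb)
  expect_error(read_annotations(pb, format = "gaf_like"), "aspect",
               class = "bioid_validation_error")
  pe <- tempfile(); writeLines("!only a comment", pe)
  expect_error(read_annotations(pe, format = "gaf_like"), "empty",
               class = "bioid_validation_error")
})

test_that("annotation write-read round-trip is the identity", {
  set.seed(7)
  genes <- sprintf("G%02d", 1:30)
  term <- rep(sprintf("T%d", 1:6), each = 8)
  gene <- sample(genes, length(term), replace = TRUE)
  ann <- annotation_set(term, gene)
  pp <- tempfile(fileext = ".tsv"); mp <- tempfile(fileext = ".tsv")
  write_annotations(ann, pp, mp)
  back <- read_annotations(pp, "two_column_tsv", term_meta_path = mp)
  expect_equal(lapply(back$term_to_genes, sort), lapply(ann$term_to_genes, sort))
  expect_equal(back$background, ann$background)
})

test_that("known-edge reader applies the confidence floor and collapses symmetry", {
  p <- write_tsv_fixture(data.frame(a = c("x", "y", "z"), b = c("y", "z", "x"),
                                    score = c(0.4, 0.5, 0.9)))
  edges <- read_known_edges(p, min_confidence = 0.5)
  expect_equal(nrow(edges), 2L)  # floor is inclusive: 0.5 retained, 0.4 dropped
  expect_true(all(edges$confidence >= 0.5))

  p2 <- write_tsv_fixture(data.frame(a = c("a", "b"), b = c("b", "a"),
                                     score = c(0.6, 0.8)))
  e2 <- read_known_edges(p2, min_confidence = 0)
  expect_equal(nrow(e2), 1L)
  expect_equal(e2$confidence, 0.8)  # reversed duplicate keeps the max

  p3 <- tempfile(fileext = ".tsv"); file.create(p3)
  expect_equal(nrow(read_known_edges(p3)), 0L)

  p4 <- write_tsv_fixture(data.frame(a = "a", b = "b", score = 700))
  expect_error(read_known_edges(p4, score_scale = "unit"),
               class = "bioid_validation_error")
  e4 <- read_known_edges(p4, score_scale = "string")
  expect_equal(e4$confidence, 0.7)
})

test_that("exclusion lists match case-insensitively and protect the bait", {
  lists <- exclusion_lists()
  expect_true(is_keratin("KRT8", lists))
  expect_true(is_keratin("krt18", lists))
  expect_false(is_keratin("KRAS", lists))  # prefix is KRT, not KR
  expect_true(is_endogenous_biotin("pcca", lists))
  expect_false(is_endogenous_biotin("EIF3D", lists))
  expect_error(exclusion_lists(bait_gene = "PCCA"),
               class = "bioid_validation_error")
})
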