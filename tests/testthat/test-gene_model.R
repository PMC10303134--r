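test_that("HGVS c. positions parse to anchors and offsets", {
  p <- parse_cdna_position(c("c.1654G>A", "c.2332-2A>T", "c.-133T>C",
                             "c.88+5G>T", "c.*1455C>T"))
  expect_equal(p$anchor_bp, c(1654L, 2332L, -133L, 88L, 1455L))
  expect_equal(p$intron_offset, c(0L, -2L, 0L, 5L, 0L))
  expect_equal(p$utr3, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(p$edit, c("G>A", "A>T", "T>C", "G>T", "C>T"))
})

test_that("non-c. and malformed descriptions are rejected by name", {
  expect_error(parse_cdna_position("p.Gly552Arg"), "p\\.Gly552Arg")
  expect_error(parse_cdna_position("g.12345A>T"), "malformed")
  expect_error(parse_cdna_position("c.G>A"), "position token")
  expect_error(parse_cdna_position("c.0A>T"), "position 0")
  expect_error(parse_cdna_position("c.123"), "edit token")
})

test_that("cdna_to_protein uses ceiling codon division and rejects UTRs", {
  m <- pam_gene_model()
  expect_equal(cdna_to_protein(1654L, m), 552L)
  expect_equal(cdna_to_protein(2108L, m), 703L)
  expect_equal(cdna_to_protein(3L, m), 1L)
  expect_equal(cdna_to_protein(c(1L, 2L, 3L, 4L), m), c(1L, 1L, 1L, 2L))
  expect_error(cdna_to_protein(-133L, m), "outside the CDS")
  expect_error(cdna_to_protein(3000L, m), "outside the CDS")
  expect_error(cdna_to_protein(parse_cdna_position("c.*1455C>T"), m), "3'UTR")
})

test_that("protein residues from cDNA anchors match the published p. names", {
  v <- pam_variant_table()
  coding <- v[v$variant_class == "coding" & !is.na(v$hgvs_p), ]
  m <- pam_gene_model()
  residues <- cdna_to_protein(coding$anchor_bp, m)
  stated <- as.integer(sub("^p\\.[A-Za-z]{3}(\\d+).*$", "\\1", coding$hgvs_p))
  expect_length(residues, 16L)
  expect_equal(residues, stated)
})

test_that("assign_domain is total and order-independent, with sentinel gaps", {
  m <- tiny_model()
  expect_equal(assign_domain(1:10, m),
               c("A", "A", "A", "A", "outside-annotated-domains",
                 "B", "B", "B", "B", "outside-annotated-domains"))
  # shuffled domain list gives the same assignment
  m2 <- gene_model("TEST", "T1", 30L, 10L,
                   data.frame(name = c("B", "A"), start_aa = c(6L, 1L),
                              end_aa = c(9L, 4L)))
  expect_equal(assign_domain(1:10, m2), assign_domain(1:10, m))
  expect_error(assign_domain(11L, m), "\\[1, 10\\]")
})

test_that("published domain labels are recovered for representative variants", {
  m <- pam_gene_model()
  expect_equal(assign_domain(cdna_to_protein(1654L, m), m), "PALcc")
  expect_equal(assign_domain(cdna_to_protein(1354L, m), m), "linker")
  expect_equal(assign_domain(cdna_to_protein(718L, m), m), "PHMcc")
})

test_that("the 16 coding variants distribute 2/4/3/7/0 over the domain map", {
  m <- pam_gene_model()
  dom <- assign_domain(cdna_to_protein(pam_coding_positions(), m), m)
  counts <- table(factor(dom, levels = m$domains$name))
  expect_equal(unname(counts[["N-terminus"]]), 2L)
  expect_equal(unname(counts[["PHMcc"]]), 4L)
  expect_equal(unname(counts[["linker"]]), 3L)
  expect_equal(unname(counts[["PALcc"]]), 7L)
  expect_equal(unname(counts[["C-terminus"]]), 0L)
})

test_that("gene model validation enforces its invariants", {
  d <- data.frame(name = "A", start_aa = 1L, end_aa = 4L)
  expect_error(gene_model("G", "T", 31L, 10L, d), "3 \\* protein_length_aa")
  expect_error(gene_model("G", "T", 30L, 10L,
                          data.frame(name = c("A", "B"), start_aa = c(1L, 4L),
                                     end_aa = c(4L, 9L))),
               "non-overlapping")
  expect_error(gene_model("G", "T", 30L, 10L,
                          data.frame(name = "A", start_aa = 1L, end_aa = 11L)),
               "within")
  expect_error(gene_model("G", "T", 30L, 10L,
                          data.frame(name = "A", start_aa = 5L, end_aa = 2L)),
               "start_aa")
})

test_that("gene models round-trip through JSON", {
  m <- tiny_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_gene_model(m, path)
  expect_equal(read_gene_model(path), m)
})

test_that("domain CDS spans use codon expansion", {
  iv <- domain_cds_intervals(tiny_model())
  expect_equal(iv$start_bp, c(1L, 16L))
  expect_equal(iv$end_bp, c(12L, 27L))
})
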