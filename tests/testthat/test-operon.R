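# Two-gene annotation with controllable exon overlap plus read builders.
# Genes are single-exon unless stated so overlap fractions are exact.

test_that("gene assignment enforces the symmetric one-third overlap rule", {
  # gene: one exon of 300 bp at 1001..1300
  gff <- write_gff(list(g1 = list(strand = "+",
                                  exons = list(c(1001, 1300)))))
  ann <- readGeneAnnotation(gff)
  mk <- function(pos, len) {
    sam <- write_sam(list(sam_record("r1", 0, pos,
                                     sprintf("%dM", len),
                                     random_seq(len))))
    readSplicedAlignments(sam)
  }
  # 90/300 = 30% overlap on both sides falls short of one-third
  expect_identical(nrow(as.data.frame(assignGenes(mk(1211, 300), ann))), 0L)
  # 102/300 = 34% on both sides passes
  a <- assignGenes(mk(1199, 300), ann)
  expect_identical(as.character(a$genes[[1]]), "g1")
  # exact equality is trivially assigned
  b <- assignGenes(mk(1001, 300), ann)
  expect_identical(as.character(b$genes[[1]]), "g1")
  expect_false(b$is_fusion)
  # exactly one third (100/300) passes "at least one-third"
  d <- assignGenes(mk(1201, 400), ann)  # overlap 100, read 400: read side 25%
  expect_identical(nrow(as.data.frame(d)), 0L)
  e <- assignGenes(mk(1201, 100), ann)  # overlap 100 = read, gene side 1/3
  expect_identical(as.character(e$genes[[1]]), "g1")
})

test_that("fusion reads order genes along the read and set the flag", {
  gff <- write_gff(list(g1 = list(strand = "+", exons = list(c(1001, 2000))),
                        g2 = list(strand = "+", exons = list(c(2401, 3400)))))
  ann <- readGeneAnnotation(gff)
  sam <- write_sam(list(
    sam_record("f1", 0, 1001, "1000M400N1000M", random_seq(2000))))
  a <- assignGenes(readSplicedAlignments(sam), ann)
  expect_true(a$is_fusion)
  expect_identical(as.character(a$genes[[1]]), c("g1", "g2"))
  # minus-strand: transcription order is right to left
  gffm <- write_gff(list(m1 = list(strand = "-", exons = list(c(1001, 2000))),
                         m2 = list(strand = "-", exons = list(c(2401, 3400)))))
  annm <- readGeneAnnotation(gffm)
  samm <- write_sam(list(
    sam_record("f2", 16, 1001, "1000M400N1000M", random_seq(2000))))
  am <- assignGenes(readSplicedAlignments(samm), annm)
  expect_identical(as.character(am$genes[[1]]), c("m2", "m1"))
})

test_that("fusion reads propagate SL within half the first gene's length", {
  # g1 spans 1001..2000 (length 1000); g2 starts 400 bp into g1's span
  # window: within 500 of g1's start
  gff1 <- write_gff(list(g1 = list(strand = "+", exons = list(c(1001, 2000))),
                         g2 = list(strand = "+", exons = list(c(1401, 2400)))))
  ann1 <- readGeneAnnotation(gff1)
  asn <- S4Vectors::DataFrame(
    read_id = "f1", genes = IRanges::CharacterList(list(c("g1", "g2"))),
    is_fusion = TRUE)
  calls <- data.frame(read_id = "f1", sl_class = "SL2",
                      category = "high_confidence_SL")
  tab <- propagateSLToGenes(asn, calls, ann1)
  expect_identical(tab[tab$gene_id == "g1", "n_SL2"], 1L)
  expect_identical(tab[tab$gene_id == "g2", "n_SL2"], 1L)  # 400 <= 500
  # g2 starting 600 bp downstream falls outside the window
  gff2 <- write_gff(list(g1 = list(strand = "+", exons = list(c(1001, 2000))),
                         g2 = list(strand = "+", exons = list(c(1601, 2600)))))
  tab2 <- propagateSLToGenes(asn, calls, readGeneAnnotation(gff2))
  expect_identical(tab2[tab2$gene_id == "g1", "n_SL2"], 1L)
  expect_identical(tab2[tab2$gene_id == "g2", "n_SL2"], 0L)
  expect_identical(tab2[tab2$gene_id == "g2", "n_total"], 1L)
})

test_that("ambiguous and single-gene reads update the right counters", {
  gff <- write_gff(list(g1 = list(strand = "+", exons = list(c(1001, 2000)))))
  ann <- readGeneAnnotation(gff)
  asn <- S4Vectors::DataFrame(
    read_id = c("a", "b", "c", "d"),
    genes = IRanges::CharacterList(list("g1", "g1", "g1", "g1")),
    is_fusion = rep(FALSE, 4))
  calls <- data.frame(
    read_id = c("a", "b", "c", "d"),
    sl_class = c("SL1", "SL2", NA, "SL1"),
    category = c("high_confidence_SL", "high_confidence_SL",
                 "high_confidence_SL", "potential_SL"))
  tab <- propagateSLToGenes(asn, calls, ann)
  # SL_unknown (NA class) and non-promoted reads add no SL evidence
  expect_identical(tab$n_SL1, 1L)
  expect_identical(tab$n_SL2, 1L)
  expect_identical(tab$n_total, 4L)
})

test_that("gene roles follow the majority and the dual-role override", {
  tab <- classifyGeneRoles(summary_table(
    list("up", 10L, 2L, 20L),     # SL1 majority, SL2 share 10%
    list("down", 3L, 7L, 30L),    # SL2 majority, SL2 share below 1/4
    list("dual", 15L, 6L, 21L),   # 6/21 > 1/4 and 6 reads ("over five")
    list("five", 15L, 5L, 19L),   # 5 reads is not "over five"
    list("quarter", 18L, 6L, 24L),# 6/24 is not > 1/4
    list("silent", 0L, 0L, 8L)))
  expect_identical(tab$role,
                   c("upstream", "downstream", "both", "upstream",
                     "upstream", "none"))
})

test_that("grouping respects the span boundary and strand", {
  gff <- write_gff(list(
    a = list(strand = "+", exons = list(c(1000, 2000))),
    b = list(strand = "+", exons = list(c(3200, 4200))),    # gap 1200
    c = list(strand = "+", exons = list(c(10200, 11200))),  # gap 6000
    d = list(strand = "-", exons = list(c(11500, 12500))),  # opposite strand
    e = list(strand = "+", exons = list(c(16200, 17200))))) # gap 5000
  ann <- readGeneAnnotation(gff)
  cl <- groupGenes(ann, span = 5000)
  key <- vapply(cl, paste, character(1), collapse = ",")
  expect_true("a,b" %in% key)            # 1200 <= 5000
  expect_true("c,e" %in% key)            # exactly 5000 still groups
  expect_true("d" %in% key)              # strand break
})

test_that("minus-strand clusters come out in transcription order", {
  gff <- write_gff(list(
    x = list(strand = "-", exons = list(c(1000, 2000))),
    y = list(strand = "-", exons = list(c(2500, 3500)))))
  cl <- groupGenes(readGeneAnnotation(gff), span = 5000)
  expect_identical(cl[[1]], c("y", "x"))
})

test_that("operon confirmation needs three SL2 reads on every downstream gene", {
  gff <- write_gff(list(
    A = list(strand = "+", exons = list(c(1000, 2000))),
    B = list(strand = "+", exons = list(c(2500, 3500)))))
  ann <- readGeneAnnotation(gff)
  cl <- groupGenes(ann, span = 5000)
  ok <- classifyGeneRoles(summary_table(list("A", 5L, 0L, 5L),
                                        list("B", 0L, 3L, 3L)))
  ops <- callOperons(cl, ok, NULL, ann)
  expect_length(ops, 1L)
  expect_identical(as.character(ops$gene_ids[[1]]), c("A", "B"))
  expect_identical(ops$evidence, "adjacency")
  low <- classifyGeneRoles(summary_table(list("A", 5L, 0L, 5L),
                                         list("B", 0L, 2L, 2L)))
  expect_length(callOperons(cl, low, NULL, ann), 0L)
})

test_that("fusion evidence needs more than three reads and an SL2 gene", {
  gff <- write_gff(list(
    A = list(strand = "+", exons = list(c(1000, 2000))),
    B = list(strand = "+", exons = list(c(2500, 3500)))))
  ann <- readGeneAnnotation(gff)
  cl <- groupGenes(ann, span = 5000)
  # roles alone cannot call the pair (B below support threshold)
  roles <- classifyGeneRoles(summary_table(list("A", 5L, 0L, 9L),
                                           list("B", 0L, 2L, 6L)))
  fus <- function(n) S4Vectors::DataFrame(
    read_id = paste0("f", seq_len(n)),
    genes = IRanges::CharacterList(rep(list(c("A", "B")), n)),
    is_fusion = rep(TRUE, n))
  expect_length(callOperons(cl, roles, fus(3L), ann), 0L)   # 3 is not > 3
  ops <- callOperons(cl, roles, fus(4L), ann)
  expect_length(ops, 1L)
  expect_identical(ops$evidence, "fusion")
  expect_identical(ops$downstream_support, 4L)
  # without any SL2-classified gene the fusion rule stays silent
  nosl2 <- classifyGeneRoles(summary_table(list("A", 5L, 0L, 9L),
                                           list("B", 1L, 0L, 6L)))
  expect_length(callOperons(cl, nosl2, fus(4L), ann), 0L)
})

test_that("operon GFF writing is deterministic and round-trips", {
  gff <- write_gff(list(
    A = list(strand = "+", exons = list(c(1000, 2000))),
    B = list(strand = "+", exons = list(c(2500, 3500)))))
  ann <- readGeneAnnotation(gff)
  cl <- groupGenes(ann, span = 5000)
  roles <- classifyGeneRoles(summary_table(list("A", 5L, 0L, 5L),
                                           list("B", 0L, 4L, 4L)))
  ops <- callOperons(cl, roles, NULL, ann)
  f1 <- tempfile(fileext = ".gff3"); f2 <- tempfile(fileext = ".gff3")
  writeOperonsGFF(ops, f1)
  writeOperonsGFF(ops, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- readOperonsGFF(f1)
  expect_identical(as.character(back$gene_ids[[1]]),
                   as.character(ops$gene_ids[[1]]))
  expect_identical(GenomicRanges::start(back), GenomicRanges::start(ops))
  expect_identical(back$downstream_support, ops$downstream_support)
  # empty call set writes a header-only file
  f3 <- tempfile(fileext = ".gff3")
  writeOperonsGFF(ops[0], f3)
  expect_identical(readLines(f3), "##gff-version 3")
  expect_length(readOperonsGFF(f3), 0L)
})

test_that("evaluation counts genes and exact structures separately", {
  mk <- function(sets) {
    gr <- GenomicRanges::GRanges(
      seqnames = "chr1",
      ranges = IRanges::IRanges(start = seq_along(sets) * 1000,
                                width = 500),
      strand = "+")
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      operon_id = paste0("op", seq_along(sets)),
      gene_ids = IRanges::CharacterList(sets),
      downstream_support = rep(3L, length(sets)),
      evidence = rep("adjacency", length(sets)))
    gr
  }
  same <- evaluateOperons(mk(list(c("a", "b"))), mk(list(c("a", "b"))))
  expect_identical(unlist(same), c(gene_precision = 1, gene_recall = 1,
                                   structure_precision = 1,
                                   structure_recall = 1))
  ev <- evaluateOperons(mk(list(c("a", "b"), c("c", "d"))),
                        mk(list(c("a", "b", "e"))))
  expect_identical(ev$gene_precision, 0.5)
  expect_equal(ev$gene_recall, 2 / 3, tolerance = 1e-12)
  # partial operon: genes count, the structure does not
  ev2 <- evaluateOperons(mk(list(c("a", "b"))), mk(list(c("a", "b", "c"))))
  expect_identical(ev2$gene_precision, 1)
  expect_identical(ev2$structure_precision, 0)
  expect_warning(
    evaluateOperons(mk(list(c("a", "b")))[0], mk(list(c("a", "b")))),
    "precision undefined")
})
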