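# TA site enumeration, phase classification, insertion and excision.

test_that("enumerate_ta_sites reproduces hand-worked phase assignments", {
  # ATG CTA GGC TAA: T at 5 (codon 2, position 2 -> P23), T at 10 (codon 4,
  # position 1 -> P12)
  ann <- data.frame(gene_id = "g", start = 1L, end = 12L, strand = "+")
  s <- enumerate_ta_sites("ATGCTAGGCTAA", ann)
  expect_identical(s$t_coord, c(5L, 10L))
  expect_identical(s$phase, c("P23", "P12"))
  expect_identical(s$cds_offset, c(5L, 10L))
  # ATG GGT ACC TAA: T at 6 (codon 2, position 3 -> P31)
  s <- enumerate_ta_sites("ATGGGTACCTAA", ann)
  expect_identical(s$phase[s$t_coord == 6L], "P31")
  # no TA at all
  expect_identical(nrow(enumerate_ta_sites("GGCCGGCC")), 0L)
  # out-of-bounds annotation
  expect_error(
    enumerate_ta_sites("ATGTAA", data.frame(gene_id = "g", start = 1L,
                                            end = 99L, strand = "+")),
    "bounds"
  )
})

test_that("sites in overlapping CDSs are reported once per CDS", {
  ann <- data.frame(gene_id = c("a", "b"), start = c(1L, 4L),
                    end = c(12L, 15L), strand = "+")
  s <- enumerate_ta_sites("ATGCTAGGCTAAGGC", ann)
  hit5 <- s[s$t_coord == 5L, ]
  expect_identical(sort(hit5$gene_id), c("a", "b"))
  expect_identical(hit5$cds_offset[hit5$gene_id == "a"], 5L)
  expect_identical(hit5$cds_offset[hit5$gene_id == "b"], 2L)
})

test_that("minus-strand CDS offsets anchor on the reading-strand T", {
  # gene on minus strand: reading sequence is revcomp(contig[start..end])
  gene <- generate_fixture_gene(8, data.frame(codon = 3L, phase = "P23"),
                                seed = 9)
  contig <- revcomp(gene$seq)
  ann <- data.frame(gene_id = "g", start = 1L, end = nchar(contig),
                    strand = "-")
  s <- enumerate_ta_sites(contig, ann)
  s <- s[s$in_cds, ]
  expect_true(gene$sites$cds_offset %in% s$cds_offset)
  expect_identical(s$phase[s$cds_offset == gene$sites$cds_offset], "P23")
})

test_that("classify_phase follows the codon-position rule on both sides of the ATG", {
  expect_identical(as.character(classify_phase(c(5L, 6L, 7L))),
                   c("P23", "P31", "P12"))
  neg <- classify_phase(c(-1L, -2L, -3L, -4L))
  expect_identical(as.character(neg), c("P31", "P23", "P12", "P31"))
  expect_identical(attr(neg, "upstream"), rep(TRUE, 4))
  # frame continuity across the (nonexistent) zero
  expect_identical(as.character(classify_phase(-1L)),
                   as.character(classify_phase(3L)))
  expect_error(classify_phase(0L), "offset 0")
})

test_that("phase partition: every in-CDS site gets exactly one phase and classes are uniform on random sequence", {
  # uniform over {A,C,G,T} (10,000 codons); a sense-codon-constrained CDS
  # would bias the phase classes
  cds <- synthetic_genome(30000, seed = 21)
  ann <- data.frame(gene_id = "g", start = 1L, end = nchar(cds), strand = "+")
  s <- enumerate_ta_sites(cds, ann)
  in_cds <- s[s$in_cds, ]
  expect_true(all(in_cds$phase %in% c("P23", "P31", "P12")))
  counts <- table(factor(in_cds$phase, levels = c("P23", "P31", "P12")))
  expect_identical(sum(counts), nrow(in_cds))
  # equinumerous in expectation: chi-square must not reject at alpha = 0.01
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("apply_insertion duplicates the TA and is inverted exactly by excise_insertion", {
  expect_identical(apply_insertion("ATGCTAGGCTAA", 5L, "CCCCCC"),
                   "ATGCTACCCCCCTAGGCTAA")
  # degenerate empty cargo only duplicates the TA
  expect_identical(apply_insertion("ATGCTAGGCTAA", 5L, ""),
                   "ATGCTATAGGCTAA")
  expect_error(apply_insertion("ATGCTAGGCTAA", 2L, "CC"), "not 'TA'")

  vs <- toy_variants()
  gene <- generate_fixture_gene(
    30, data.frame(codon = c(5L, 12L, 20L), phase = c("P23", "P31", "P12")),
    seed = 13
  )
  for (i in seq_len(nrow(gene$sites))) {
    for (v in vs) {
      cargo <- build_cargo(v)
      for (orient in c("forward", "reverse")) {
        mut <- apply_insertion(gene$seq, gene$sites$t_coord[i], cargo,
                               orientation = orient)
        expect_identical(nchar(mut),
                         nchar(gene$seq) + nchar(cargo$residues) + 2L)
        # nothing outside the insertion interval changes
        t <- gene$sites$t_coord[i]
        expect_identical(substr(mut, 1, t + 1), substr(gene$seq, 1, t + 1))
        expect_identical(substr(mut, nchar(mut) - (nchar(gene$seq) - t - 2),
                                nchar(mut)),
                         substr(gene$seq, t + 2, nchar(gene$seq)))
        # exact round trip
        expect_identical(
          excise_insertion(mut, t, nchar(cargo$residues)), gene$seq
        )
      }
    }
  }
})

test_that("excise_insertion rejects inconsistent junctions", {
  mut <- apply_insertion("ATGCTAGGCTAA", 5L, "CCCCCC")
  expect_error(excise_insertion(mut, 5L, 5L), "integrity error")
  expect_error(excise_insertion(mut, 5L, 7L), "integrity error")
  expect_error(excise_insertion("ATGCTAGGCTAA", 5L, 6L), "integrity error")
})
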