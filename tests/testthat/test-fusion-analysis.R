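# ORF verification, fusion protein prediction and gene/genome scanning.

test_that("verify_orf distinguishes continuous from interrupted frames", {
  # open1 at a P23 site with stop-free toy components: continuous
  v1 <- transposon_variant("open1", "GGTGGC", itr_up = strrep("A", 27),
                          itr_down = strrep("A", 27))
  mut <- apply_insertion("ATGCTAGGCTAA", 5L, build_cargo(v1))
  res <- verify_orf(mut, 1L, expected_len = 24L)
  expect_true(res$continuous)
  expect_identical(res$first_stop, 25L)

  # P12 insertion with an unmodified A-starting ITR: immediate TAA stop at
  # the junction
  v3 <- transposon_variant("open3", "GGTGGC", itr_up = strrep("A", 27),
                           itr_down = strrep("A", 27))
  gene <- "ATGGGCTACGGCTAA"           # TA at 7-8, codon 3 positions 1-2
  mut <- verify_orf(apply_insertion(gene, 7L, build_cargo(v3)), 1L,
                    expected_len = 25L)
  expect_false(mut$continuous)
  expect_identical(mut$first_stop, 3L)  # codon 3 reads TAA
  expect_error(verify_orf("GGGTAA", 1L, 1L), "no ATG")
})

test_that("the worked 24-residue sandwich fusion is reproduced with full segment bookkeeping", {
  v <- transposon_variant("open1", "GGTGGC", itr_up = strrep("A", 27),
                          itr_down = strrep("A", 27))
  fus <- predict_fusion_protein("ATGCTAGGCTAA", 5L, v)
  # independent oracle: translate the constructed nucleotide sequence
  manual <- paste0("ATGCTA", strrep("A", 27), "GGTGGC", "A", strrep("A", 27),
                   "TA", "GGCTAA")
  expect_identical(fus$mutated, manual)
  aa <- translate_dna(manual)
  expect_identical(fus$protein, substr(aa, 1, nchar(aa) - 1))
  expect_identical(nchar(fus$protein), 24L)
  expect_identical(fus$protein, "MLKKKKKKKKKGGKKKKKKKKKIG")
  expect_true(fus$productive)
  expect_true(is.na(fus$premature_stop))
  # segment map tiles the protein exactly
  seg <- fus$segments
  expect_identical(seg$start[1], 1L)
  expect_identical(seg$end[nrow(seg)], nchar(fus$protein))
  expect_identical(seg$start[-1], seg$end[-nrow(seg)] + 1L)
  expect_identical(
    seg$segment,
    c("target_N", "itr_up_linker", "reporter", "itr_down_linker", "target_C")
  )
  # frame restoration: target_C equals the wild-type residues downstream
  expect_identical(substr(fus$protein, seg$start[5], seg$end[5]), "G")
})

test_that("upstream (negative offset) insertions give reporter-first fusions when in frame", {
  cds <- generate_fixture_gene(10, seed = 31)$seq
  wt_aa <- translate_dna(cds)
  # TA placed so that gap = cds_start - t - 2 is a multiple of 3 (open1)
  prefix <- paste0(strrep("G", 22), "TA", "GGCGGC")   # t = 23, cds at 31
  gene <- paste0(prefix, cds)
  v <- toy_variants()$open1
  fus <- predict_fusion_protein(gene, 23L, v, cds_start = 31L,
                                cds_end = 30L + nchar(cds))
  expect_identical(fus$topology, "n_terminal")
  expect_identical(fus$cds_offset, -8L)
  expect_true(fus$productive)
  expect_identical(fus$segments$segment[1], "reporter")
  # the intact target protein forms the C terminus
  target_wt <- substr(wt_aa, 1, nchar(wt_aa) - 1)
  expect_identical(substr(fus$protein, nchar(fus$protein) - nchar(target_wt) + 1,
                          nchar(fus$protein)),
                   target_wt)
  # shifting the site by one base breaks the frame
  gene_shift <- paste0(strrep("G", 21), "TA", "GGCGGCG", cds)
  fus_shift <- predict_fusion_protein(gene_shift, 22L, v, cds_start = 31L,
                                      cds_end = 30L + nchar(cds))
  expect_false(fus_shift$productive)
  expect_error(
    predict_fusion_protein(gene, 23L, v, orientation = "antisense"),
    "antisense"
  )
})

test_that("scan_gene finds one productive pair per planted phase", {
  gene <- generate_fixture_gene(
    30, data.frame(codon = c(5L, 12L, 20L), phase = c("P23", "P31", "P12")),
    seed = 17
  )
  vs <- toy_variants()
  rows <- scan_gene(gene$seq, vs)
  expect_identical(nrow(rows), 9L)                  # 3 sites x 3 variants
  expect_identical(sum(rows$compatible), 3L)
  expect_identical(sum(rows$productive), 3L)
  prod <- rows[rows$productive, ]
  expect_identical(sort(prod$phase), c("P12", "P23", "P31"))
  expect_identical(unname(phase_to_variant(prod$phase)), prod$variant)
  # zero TA sites -> zero rows; partial CDS -> skipped with warning
  expect_identical(nrow(scan_gene(generate_fixture_gene(5, seed = 1)$seq, vs)),
                   0L)
  expect_warning(out <- scan_gene("ATGCTAGG", vs), "partial CDS")
  expect_identical(nrow(out), 0L)
})

test_that("phase-arithmetic productivity equals brute-force translation (oracle equivalence)", {
  vs <- toy_variants()
  n_pairs <- 0L
  # gene seeds disjoint from the reporter seed: the oracle's reporter-peptide
  # check must not find the peptide encoded in the target itself
  for (seed in 201:206) {
    gene <- synthetic_cds(120, seed = seed)
    ann <- data.frame(gene_id = "g", start = 1L, end = nchar(gene),
                      strand = "+")
    sites <- enumerate_ta_sites(gene, ann)
    sites <- sites[sites$in_cds, ]
    for (i in seq_len(nrow(sites))) {
      for (v in vs) {
        fast <- identical(v$compatible_phase, sites$phase[i])
        full <- oracle_productive(gene, sites$t_coord[i], v)
        expect_identical(fast, full,
                         info = sprintf("seed %d t %d %s", seed,
                                        sites$t_coord[i], v$name))
        fus <- predict_fusion_protein(gene, sites$t_coord[i], v)
        expect_identical(fus$productive, full)
        n_pairs <- n_pairs + 1L
      }
    }
  }
  expect_gt(n_pairs, 150)
})

test_that("mismatched variant/phase pairs never translate the reporter in its designed frame", {
  gene <- generate_fixture_gene(
    40, data.frame(codon = c(6L, 15L, 25L), phase = c("P23", "P31", "P12")),
    seed = 23
  )
  vs <- toy_variants()
  # exhaustive over the 6 mismatched (phase, variant) pairs
  for (i in seq_len(nrow(gene$sites))) {
    for (v in vs) {
      if (identical(v$compatible_phase, gene$sites$phase[i])) next
      t <- gene$sites$t_coord[i]
      fus <- predict_fusion_protein(gene$seq, t, v)
      expect_false(fus$productive)
      expect_false(oracle_productive(gene$seq, t, v))
      # the frame shift garbles the reporter peptide even when, as with the
      # all-{C,A} toy ITR, no stop codon happens to arise
      expect_false(grepl(translate_dna(v$reporter), fus$protein,
                         fixed = TRUE))
    }
  }
})

test_that("scan_genome aggregates per-gene scans additively", {
  g1 <- generate_fixture_gene(20, data.frame(codon = 4L, phase = "P23"),
                              seed = 3)
  g2 <- generate_fixture_gene(25, data.frame(codon = c(5L, 10L),
                                             phase = c("P31", "P12")),
                              seed = 4)
  genome <- c(c1 = g1$seq, c2 = g2$seq)
  ann <- data.frame(
    gene_id = c("g1", "g2"), contig_id = c("c1", "c2"),
    start = 1L, end = c(nchar(g1$seq), nchar(g2$seq)), strand = "+",
    partial = FALSE
  )
  vs <- toy_variants()
  rep <- scan_genome(genome, ann, vs)
  expect_identical(rep$summary$n_sites, 3L)
  expect_identical(rep$summary$n_productive, 3L)
  expect_identical(as.integer(rep$summary$per_gene[c("g1", "g2")]), c(1L, 2L))
  # single gene genome equals scan_gene
  rep1 <- scan_genome(genome["c1"], ann[1, ], vs)
  expect_identical(rep1$rows, scan_gene(g1$seq, vs, gene_id = "g1"))
})

test_that("phase fractions on a large uniform-random fixture are near one third each", {
  # uniform over {A,C,G,T}: a stop-free CDS would deplete P12 sites (TAA/TAG
  # exclusion), so the uniformity claim is about unconstrained sequence
  cds <- synthetic_genome(24000, seed = 41)
  ann <- data.frame(gene_id = "g", start = 1L, end = nchar(cds), strand = "+")
  s <- enumerate_ta_sites(cds, ann)
  frac <- prop.table(table(s$phase[s$in_cds]))
  expect_true(all(abs(frac - 1 / 3) < 0.05))
})

test_that("dedup_candidates keeps first occurrences by key", {
  rows <- data.frame(
    gene_id = c("a", "a", "b", "a"),
    cds_offset = c(5L, 5L, 5L, 9L),
    note = c("first", "dup", "other-gene", "new")
  )
  out <- dedup_candidates(rows)
  expect_identical(out$note, c("first", "other-gene", "new"))
  expect_identical(nrow(dedup_candidates(rows[0, ])), 0L)
  same <- rows[rep(1, 7), ]
  expect_identical(nrow(dedup_candidates(same)), 1L)
})
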