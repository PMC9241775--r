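# Split-fluorophore BiFC construct design.

test_that("split_fluorophore reproduces the canonical 462/255 bp split", {
  cds <- synthetic_reporter(239, seed = 8)   # 717 nt, stop-free
  expect_identical(nchar(cds), 717L)
  sp <- split_fluorophore(cds, 154L)
  expect_identical(sp$n_len_bp, 462L)
  expect_identical(sp$c_len_bp, 255L)
  expect_identical(sp$c_len_aa, 85L)
  expect_identical(paste0(sp$frag_n_cds, sp$frag_c_cds), cds)
})

test_that("split/join identity holds for all valid split points and ranges are enforced", {
  cds <- synthetic_reporter(30, seed = 12)
  for (k in seq_len(29)) {
    sp <- split_fluorophore(cds, k)
    expect_identical(paste0(sp$frag_n_cds, sp$frag_c_cds), cds)
    expect_identical(sp$n_len_bp, 3L * k)
  }
  sp1 <- split_fluorophore(cds, 1L)
  expect_identical(sp1$frag_n_cds, substr(cds, 1, 3))
  expect_error(split_fluorophore(cds, 0L), "strictly inside")
  expect_error(split_fluorophore(cds, 30L), "strictly inside")
  expect_error(split_fluorophore(paste0(cds, "TAA"), 5L), "stop codon")
  expect_error(split_fluorophore(substr(cds, 1, 10), 2L), "multiple of 3")
})

test_that("build_bait makes an in-frame stop-free construct and rejects bad parts", {
  sp <- split_fluorophore(synthetic_reporter(239, seed = 8), 154L)
  target <- "ATGGGCCGT"
  bait <- build_bait(target, sp)
  expect_identical(nchar(bait$seq), 9L + 462L + 3L)
  aa <- translate_dna(bait$seq)
  expect_identical(regexpr("*", aa, fixed = TRUE)[1], nchar(aa))
  # a terminal stop on the target is stripped at the junction
  bait2 <- build_bait(paste0(target, "TAA"), sp)
  expect_identical(bait2$seq, bait$seq)
  expect_error(build_bait(target, sp, linker = "GGCC"), "frame error")
  expect_error(build_bait("ATGTAAGGC", sp), "internal stop codon at residue 2")
})

test_that("prey transposons carry the C fragment and pass variant validation", {
  sp <- split_fluorophore(synthetic_reporter(239, seed = 8), 154L)
  itr <- strrep("A", 27)
  p1 <- build_prey_transposon("open1", sp, itr_up = itr, itr_down = itr)
  expect_identical(nchar(build_cargo(p1)$residues), 27L + 0L + 255L + 1L + 27L)
  p2 <- build_prey_transposon("open2", sp, itr_up = itr, itr_down = itr)
  expect_identical(nchar(build_cargo(p2)$residues), 27L + 2L + 255L + 2L + 27L)
  expect_true(attr(validate_variant(p1), "valid"))
  expect_true(attr(validate_variant(p2), "valid"))
  # open3 prey refused unless overridden
  expect_error(build_prey_transposon("open3", sp), "open3 prey refused")
  p3 <- build_prey_transposon("open3", sp, allow_open3 = TRUE,
                              itr_up = itr, itr_down = itr)
  expect_true(attr(validate_variant(p3), "valid"))
  # a fragment ending in a stop codon violates the reporter invariant
  bad <- sp
  bad$frag_c_cds <- paste0(substr(sp$frag_c_cds, 1, 252), "TAA")
  expect_error(build_prey_transposon("open1", bad, itr_up = itr,
                                     itr_down = itr),
               "reporter")
})

test_that("self-insertion into the bait reorders the fluorophore fragments", {
  sp <- split_fluorophore(synthetic_reporter(239, seed = 8), 154L)
  target <- generate_fixture_gene(40, data.frame(codon = 12L, phase = "P23"),
                                  seed = 19)
  bait <- build_bait(target$seq, sp)
  res <- detect_self_insertion(bait, target$sites$t_coord)
  expect_true(res$within_bait)
  expect_identical(res$insertion_segment, "target")
  expect_identical(res$topology, c("target_N", "fragC", "target_C", "frag_n"))
  # insertion within the N fragment
  frag_n_seg <- bait$segments[bait$segments$segment == "frag_n", ]
  ta_in_fragn <- enumerate_ta_sites(bait$seq)
  ta_in_fragn <- ta_in_fragn[ta_in_fragn$t_coord >= frag_n_seg$start &
                               ta_in_fragn$t_coord + 1 <= frag_n_seg$end, ]
  expect_gt(nrow(ta_in_fragn), 0)
  res2 <- detect_self_insertion(bait, ta_in_fragn$t_coord[1])
  expect_identical(res2$insertion_segment, "frag_n")
  expect_identical(res2$topology[1], "target")
  expect_true(all(c("frag_n_N", "fragC", "frag_n_C") %in% res2$topology))
  # downstream of the stop: not within the bait
  expect_false(detect_self_insertion(bait, nchar(bait$seq) + 5L)$within_bait)
})

test_that("a productive prey insertion into a bait gene yields one continuous ORF through the C fragment", {
  sp <- split_fluorophore(synthetic_reporter(239, seed = 8), 154L)
  target <- generate_fixture_gene(40, data.frame(codon = 12L, phase = "P23"),
                                  seed = 19)
  bait <- build_bait(target$seq, sp)
  prey <- build_prey_transposon("open1", sp, itr_up = toy_itr(),
                                itr_down = toy_itr())
  fus <- predict_fusion_protein(bait$seq, target$sites$t_coord, prey,
                                gene_id = "bait")
  expect_true(fus$productive)
  expect_true(is.na(fus$premature_stop))
  expect_identical(
    fus$segments$segment,
    c("target_N", "itr_up_linker", "reporter", "itr_down_linker", "target_C")
  )
})
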