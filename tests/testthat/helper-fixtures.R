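# Shared fixtures and independent oracles for the test suite.

# 27-bp ITR over {C,A} only: stop-free in every junction frame (no T or G
# means no codon can be a stop regardless of phase).
toy_itr <- function() strrep("CCA", 9L)

# Stock variant set sharing one reporter and the stop-free toy ITR.
toy_variants <- function(reporter = synthetic_reporter(10L, seed = 2L),
                         include_open3 = TRUE) {
  stock_variants(reporter, include_open3 = include_open3,
                 itr_up = toy_itr(), itr_down = toy_itr())
}

# Brute-force productivity oracle, independent of the phase arithmetic and of
# predict_fusion_protein: assemble the mutated CDS by string concatenation,
# translate it, and demand (i) the first stop is exactly the final codon,
# (ii) the reporter's designed (frame-0) peptide appears intact in the
# translation — the cargo plus TA duplication is always a multiple of 3, so
# the downstream target frame is restored for any phase; what a mismatched
# phase shifts is the reporter's own frame — and (iii) the residues
# downstream of the cargo equal the wild-type residues.
oracle_productive <- function(gene, t_coord, variant,
                              cds_start = 1L, cds_end = nchar(gene)) {
  cargo <- paste0(variant$itr_up, variant$spacer5, variant$reporter,
                  variant$spacer3, variant$itr_down)
  mutated_cds <- paste0(
    substr(gene, cds_start, t_coord + 1L), cargo, "TA",
    substr(gene, t_coord + 2L, cds_end)
  )
  aa <- translate_dna(mutated_cds)
  n_res <- nchar(aa)
  first_stop <- regexpr("*", aa, fixed = TRUE)
  if (first_stop != n_res) return(FALSE)  # premature stop or missing stop
  if (!grepl(translate_dna(variant$reporter), aa, fixed = TRUE)) {
    return(FALSE)                         # reporter read out of frame
  }
  # wild-type residues encoded by complete codons strictly downstream of the
  # original TA
  wt_aa <- translate_dna(substr(gene, cds_start, cds_end))
  o2 <- t_coord + 2L - cds_start + 1L          # CDS offset of first base after TA
  first_codon <- if ((o2 - 1L) %% 3L == 0L) (o2 + 2L) %/% 3L else
    (o2 + 2L) %/% 3L + 1L
  tail_wt <- substr(wt_aa, first_codon, nchar(wt_aa) - 1L)
  if (nchar(tail_wt) == 0L) return(TRUE)
  identical(substr(aa, n_res - nchar(tail_wt), n_res - 1L), tail_wt)
}

# A random genome in which every TA-leading k-mer is unique across both
# strands, so tag mapping must recover every insertion unambiguously.
# Deterministic: scans seed offsets from `seed` until a clean genome is found.
repeat_free_genome <- function(n_bases = 2000L, k = 10L, seed = 101L) {
  all_kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }
  for (off in 0:200) {
    g <- synthetic_genome(n_bases, seed = seed + off)
    km <- c(all_kmers(g), all_kmers(revcomp(g)))
    ta <- km[startsWith(km, "TA")]
    counts <- table(km)
    if (length(ta) >= 110L && all(counts[unique(ta)] == 1L)) return(g)
  }
  stop("no repeat-free genome found in 200 attempts")
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")

cli_path <- function() system.file("cli", "tnfusion", package = "tnfusion")

run_cli <- function(...) {
  out <- tempfile()
  err <- tempfile()
  status <- system2(rscript_bin(), c(cli_path(), ...),
                    stdout = out, stderr = err)
  list(status = status,
       stdout = readLines(out, warn = FALSE),
       stderr = readLines(err, warn = FALSE))
}
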