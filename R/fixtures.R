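# Synthetic fixture generation: CDSs with TA sites at prescribed codon
# phases, stop-free CDSs, and random genomes. These stand in for the
# "theoretical sequence" cartoons used to reason about frame-preserving
# insertion, and feed every property test in the package.

# Filler codons drawn only from {C,G}: stop-free, TA-free, and incapable of
# forming a TA dinucleotide across any codon boundary.
FILLER_CODONS <- c("CCG", "CGC", "GCC", "GGC", "GCG", "CGG", "CCC", "GGG")

#' Generate a fixture gene with TA sites at prescribed codon phases
#'
#' Builds a CDS starting with ATG, ending with TGA, free of internal stops,
#' and containing TA dinucleotides at exactly the requested codon phases and
#' ordinal codon positions. All other codons come from a stop-free, TA-free
#' codon set so no accidental TA site can arise, including across codon
#' boundaries.
#'
#' Phase encodings (positions of the target TA within the codon grid):
#' * `P23`: T and A at positions 2-3 of the named codon (`XTA`).
#' * `P31`: T at position 3 of the named codon, A at position 1 of the next
#'   (`XXT-AXX`); this consumes the following codon as well.
#' * `P12`: T and A at positions 1-2 of the named codon (`TAX`).
#'
#' @param n_codons Total codon count including start and stop (>= 3).
#' @param sites Optional data.frame with columns `codon` (ordinal position)
#'   and `phase` (`"P23"`, `"P31"`, `"P12"`), or NULL for no internal TA site.
#' @param seed Optional integer seed; the output is deterministic for a given
#'   seed and spec.
#' @return A list with elements `seq` (the CDS), `sites` (data.frame with
#'   `t_coord`, `cds_offset`, `phase`), and `n_codons`.
#' @export
generate_fixture_gene <- function(n_codons, sites = NULL, seed = NULL) {
  n_codons <- as.integer(n_codons)
  if (n_codons < 3L) stop("n_codons must be >= 3", call. = FALSE)
  if (is.null(sites)) {
    sites <- data.frame(codon = integer(0), phase = character(0))
  }
  stopifnot(all(c("codon", "phase") %in% names(sites)))
  if (nrow(sites)) {
    sites <- sites[order(sites$codon), , drop = FALSE]
    if (!all(sites$phase %in% c("P23", "P31", "P12"))) {
      stop("unknown phase label in site request", call. = FALSE)
    }
    if (any(sites$codon <= 1L | sites$codon >= n_codons)) {
      stop("requested site falls in the start or stop codon: unsatisfiable",
           call. = FALSE)
    }
    if (any(sites$phase == "P31" & sites$codon >= n_codons - 1L)) {
      stop("P31 site needs a following non-stop codon: unsatisfiable",
           call. = FALSE)
    }
    if (anyDuplicated(sites$codon)) {
      stop("multiple sites requested in the same codon", call. = FALSE)
    }
    follow <- sites$codon[sites$phase == "P31"] + 1L
    if (any(follow %in% sites$codon)) {
      stop("P31 site consumes the following codon, which is also requested",
           call. = FALSE)
    }
  }
  with_seed(seed, {
    codons <- sample(FILLER_CODONS, n_codons, replace = TRUE)
    codons[1L] <- "ATG"
    codons[n_codons] <- "TGA"
    for (i in seq_len(nrow(sites))) {
      k <- sites$codon[i]
      codons[k] <- switch(sites$phase[i],
        P23 = paste0(sample(c("C", "G"), 1L), "TA"),
        P12 = paste0("TA", sample(c("C", "T"), 1L)),
        P31 = paste0(sample(c("CC", "GG", "CG", "GC"), 1L), "T")
      )
      if (sites$phase[i] == "P31") {
        codons[k + 1L] <- paste0("A", sample(c("CC", "GC", "CG", "GG"), 1L))
      }
    }
    seq <- paste(codons, collapse = "")
    t_coord <- vapply(seq_len(nrow(sites)), function(i) {
      k <- as.integer(sites$codon[i])
      switch(sites$phase[i],
        P23 = (k - 1L) * 3L + 2L,
        P31 = (k - 1L) * 3L + 3L,
        P12 = (k - 1L) * 3L + 1L
      )
    }, integer(1))
    list(
      seq = seq,
      sites = data.frame(
        t_coord = t_coord,
        cds_offset = t_coord,
        phase = if (nrow(sites)) sites$phase else character(0),
        stringsAsFactors = FALSE
      ),
      n_codons = n_codons
    )
  })
}

#' Generate a random stop-free CDS
#'
#' A CDS of `n_codons` codons starting ATG and ending TAA with no internal
#' stop codon in frame 0; internal codons are uniform over the 61 sense
#' codons. Used as a random substrate for property tests and as a synthetic
#' reporter source (see [synthetic_reporter()]).
#'
#' @param n_codons Total codon count including start and stop (>= 3).
#' @param seed Optional integer seed.
#' @return The CDS as a character scalar.
#' @export
synthetic_cds <- function(n_codons, seed = NULL) {
  n_codons <- as.integer(n_codons)
  if (n_codons < 3L) stop("n_codons must be >= 3", call. = FALSE)
  sense <- setdiff(
    apply(expand.grid(DNA_ALPHABET[1:4], DNA_ALPHABET[1:4],
                      DNA_ALPHABET[1:4]), 1, paste, collapse = ""),
    c("TAA", "TAG", "TGA")
  )
  with_seed(seed, {
    paste(c("ATG", sample(sense, n_codons - 2L, replace = TRUE), "TAA"),
          collapse = "")
  })
}

#' Generate a stop-free reporter coding sequence
#'
#' A reporter cassette body: length a multiple of 3, no stop codon in frame 0
#' anywhere (including the end), suitable as the reporter of a transposon
#' variant, which by design lacks a stop codon that would arrest translation
#' within the transposon.
#'
#' @param n_codons Number of reporter codons.
#' @param seed Optional integer seed.
#' @return The reporter CDS as a character scalar.
#' @export
synthetic_reporter <- function(n_codons, seed = NULL) {
  n_codons <- as.integer(n_codons)
  if (n_codons < 1L) stop("n_codons must be >= 1", call. = FALSE)
  body <- synthetic_cds(n_codons + 2L, seed = seed)
  substr(body, 4L, 3L + 3L * n_codons)
}

#' Generate a random genome sequence
#'
#' Uniform over A, C, G, T. TA dinucleotides occur at the random expectation
#' of one per 16 positions; useful as a mapping target for tag round-trip
#' tests.
#'
#' @param n_bases Genome length.
#' @param seed Optional integer seed.
#' @return A character scalar of length `n_bases`.
#' @export
synthetic_genome <- function(n_bases, seed = NULL) {
  with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), as.integer(n_bases), replace = TRUE),
          collapse = "")
  })
}
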