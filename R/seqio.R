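# Sequence and annotation I/O plus core nucleotide operations.
#
# Sequences are plain upper-case character strings over {A,C,G,T,N}; named
# character vectors carry multi-record sets (names = record ids). All
# user-facing coordinates are 1-based inclusive (GFF convention).

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Normalise and validate a nucleotide sequence
#'
#' Upper-cases the input and checks that it only contains A, C, G, T or N.
#'
#' @param x Character vector of nucleotide sequences.
#' @param what Label used in error messages.
#' @return The validated upper-case character vector.
#' @export
as_dna <- function(x, what = "sequence") {
  nm <- names(x)
  x <- toupper(as.character(x))
  names(x) <- nm
  bad <- gregexpr("[^ACGTN]", x)
  for (i in seq_along(x)) {
    if (bad[[i]][1] != -1L) {
      stop(sprintf(
        "%s %s contains illegal character '%s' at position %d",
        what, if (!is.null(names(x))) names(x)[i] else i,
        substr(x[i], bad[[i]][1], bad[[i]][1]), bad[[i]][1]
      ), call. = FALSE)
    }
  }
  x
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case sequences; names are the
#'   header text up to the first whitespace. An empty file yields an empty
#'   vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(txt)))) return(setNames(character(0), character(0)))
  if (!startsWith(trimws(txt[nzchar(trimws(txt))][1]), ">")) {
    stop("malformed FASTA: first non-empty line of ", path,
         " is not a '>' header", call. = FALSE)
  }
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  as_dna(seqs, what = "FASTA record")
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- as_dna(seqs)
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs) %||% paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(path)
}

#' Read CDS features from a GFF3 file
#'
#' Returns CDS features only, with 1-based inclusive coordinates as in the
#' file. A CDS whose length is not a multiple of 3 is flagged `partial` (with
#' a warning) and should be excluded from phase analysis.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `gene_id`, `contig_id`, `start`, `end`,
#'   `strand`, `partial`.
#' @export
read_gff_cds <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "CDS"]
  if (length(gr) == 0) {
    return(data.frame(
      gene_id = character(0), contig_id = character(0),
      start = integer(0), end = integer(0), strand = character(0),
      partial = logical(0), stringsAsFactors = FALSE
    ))
  }
  mc <- S4Vectors::mcols(gr)
  pick <- function(col) {
    if (!col %in% colnames(mc)) return(rep(NA_character_, length(gr)))
    v <- mc[[col]]
    if (methods::is(v, "CharacterList") || is.list(v)) {
      v <- vapply(v, function(x) if (length(x)) as.character(x[[1]]) else NA_character_,
                  character(1))
    }
    as.character(v)
  }
  gene_id <- pick("ID")
  for (alt in c("Parent", "gene_id", "locus_tag", "Name")) {
    miss <- is.na(gene_id)
    if (!any(miss)) break
    gene_id[miss] <- pick(alt)[miss]
  }
  gene_id[is.na(gene_id)] <- paste0("cds_", which(is.na(gene_id)))
  out <- data.frame(
    gene_id = gene_id,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    partial = (GenomicRanges::width(gr) %% 3L) != 0L,
    stringsAsFactors = FALSE
  )
  if (any(out$partial)) {
    warning(sum(out$partial), " CDS feature(s) have length not a multiple of 3;",
            " flagged partial and excluded from phase analysis", call. = FALSE)
  }
  out
}

#' Write CDS annotations to a GFF3 file
#'
#' @param cds A data.frame as returned by [read_gff_cds()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff_cds <- function(cds, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = cds$contig_id,
    ranges = IRanges::IRanges(start = cds$start, end = cds$end),
    strand = cds$strand
  )
  gr$type <- "CDS"
  gr$ID <- cds$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Translate a nucleotide sequence
#'
#' Standard bacterial genetic code, frame scan semantics: translation proceeds
#' codon by codon from `frame_offset`, stop codons are rendered `*` and
#' translation continues, a trailing partial codon is dropped, and any codon
#' containing N is rendered `X`.
#'
#' @param seq A nucleotide sequence (character scalar).
#' @param frame_offset 0, 1 or 2: number of bases skipped before the first
#'   codon.
#' @return Amino-acid sequence as a character scalar (possibly empty).
#' @export
translate_dna <- function(seq, frame_offset = 0L) {
  stopifnot(frame_offset %in% 0:2)
  seq <- as_dna(seq)
  s <- substr(seq, frame_offset + 1L, nchar(seq))
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  starts <- frame_offset + 3L * (seq_len(n) - 1L) + 1L
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(CODON_TABLE[codons])
  aa[is.na(aa)] <- "X"   # any codon containing N
  paste(aa, collapse = "")
}

# standard (bacterial) genetic code, taken from Biostrings
CODON_TABLE <- c(Biostrings::GENETIC_CODE)

#' Reverse complement
#'
#' `revcomp(revcomp(s))` is the identity; note `"TA"` is its own reverse
#' complement, which is why Himar TA target sites exist on both strands at the
#' same coordinates.
#'
#' @param seq A nucleotide sequence (character scalar, may be empty).
#' @return The reverse complement.
#' @export
revcomp <- function(seq) {
  seq <- as_dna(seq)
  if (nchar(seq) == 0L) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
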