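# TA target-site enumeration, codon-phase classification, and insertion
# construction with target-site duplication.
#
# Coordinate conventions (all 1-based inclusive):
#   t_coord     position of the T of a TA dinucleotide on the forward strand
#   cds_offset  position of the reading-strand T within the CDS, with the
#               first base of ATG at +1 and the base immediately 5' of it at
#               -1 (there is no offset 0)

#' Classify the codon phase of a CDS offset
#'
#' For positive offsets the position-in-codon is `p = ((offset - 1) mod 3) + 1`
#' and `p = 2 -> P23`, `p = 3 -> P31`, `p = 1 -> P12`. Negative offsets
#' (upstream of the start codon, counted -1, -2, ... leftward with no zero)
#' are classified by extending the reading frame leftward from the ATG; the
#' result carries a logical `upstream` attribute.
#'
#' @param cds_offset Integer vector of nonzero offsets.
#' @return Character vector of phase labels with attribute `upstream`.
#' @export
classify_phase <- function(cds_offset) {
  cds_offset <- as.integer(cds_offset)
  if (any(cds_offset == 0L, na.rm = TRUE)) {
    stop("cds_offset 0 does not exist (offsets are -1, +1 around the ATG)",
         call. = FALSE)
  }
  shifted <- ifelse(cds_offset > 0L, cds_offset, cds_offset + 1L)
  p <- ((shifted - 1L) %% 3L) + 1L
  phase <- c("P12", "P23", "P31")[p]
  phase[is.na(cds_offset)] <- NA_character_
  attr(phase, "upstream") <- !is.na(cds_offset) & cds_offset < 0L
  phase
}

# cds_offset of the reading-strand T for a TA at forward t_coord within a CDS.
# On the minus strand the reading-strand T sits at forward coordinate
# t_coord + 1 (TA is its own reverse complement).
cds_offset_for_site <- function(t_coord, start, end, strand) {
  if (identical(strand, "-")) end - t_coord else t_coord - start + 1L
}

#' Enumerate TA target sites
#'
#' Reports every TA occurrence on the forward strand exactly once (TA is its
#' own reverse complement, so forward enumeration covers both strands). A site
#' whose two bases both fall inside a CDS is annotated with that CDS's
#' `gene_id`, `cds_offset` and phase; a site inside several overlapping CDSs
#' yields one row per CDS. Partial CDSs (length not a multiple of 3) are
#' skipped for annotation.
#'
#' @param seq Nucleotide sequence (character scalar).
#' @param annotations Optional CDS data.frame as from [read_gff_cds()]
#'   (columns `gene_id`, `start`, `end`, `strand`, optionally `contig_id` and
#'   `partial`).
#' @param contig_id Contig name recorded in the output (and matched against
#'   `annotations$contig_id` when present).
#' @return A data.frame with columns `contig_id`, `t_coord`, `in_cds`,
#'   `gene_id`, `gene_strand`, `cds_offset`, `phase`.
#' @export
enumerate_ta_sites <- function(seq, annotations = NULL, contig_id = "seq") {
  seq <- as_dna(seq)
  t_coord <- if (nchar(seq) < 2L) integer(0) else {
    Biostrings::start(Biostrings::matchPattern("TA", Biostrings::DNAString(seq)))
  }
  base <- data.frame(
    contig_id = rep(contig_id, length(t_coord)),
    t_coord = as.integer(t_coord),
    in_cds = rep(FALSE, length(t_coord)),
    gene_id = rep(NA_character_, length(t_coord)),
    gene_strand = rep(NA_character_, length(t_coord)),
    cds_offset = rep(NA_integer_, length(t_coord)),
    phase = rep(NA_character_, length(t_coord)),
    stringsAsFactors = FALSE
  )
  if (is.null(annotations) || nrow(annotations) == 0L || nrow(base) == 0L) {
    return(base)
  }
  ann <- annotations
  if ("contig_id" %in% names(ann)) {
    ann <- ann[ann$contig_id == contig_id, , drop = FALSE]
  }
  if ("partial" %in% names(ann)) ann <- ann[!ann$partial, , drop = FALSE]
  if (nrow(ann) && any(ann$end > nchar(seq) | ann$start < 1L)) {
    stop("annotation outside sequence bounds", call. = FALSE)
  }
  out <- list(base)
  hit_any <- rep(FALSE, nrow(base))
  for (i in seq_len(nrow(ann))) {
    inside <- base$t_coord >= ann$start[i] & (base$t_coord + 1L) <= ann$end[i]
    if (!any(inside)) next
    hit_any <- hit_any | inside
    rows <- base[inside, , drop = FALSE]
    rows$in_cds <- TRUE
    rows$gene_id <- ann$gene_id[i]
    rows$gene_strand <- ann$strand[i]
    rows$cds_offset <- as.integer(cds_offset_for_site(
      rows$t_coord, ann$start[i], ann$end[i], ann$strand[i]
    ))
    rows$phase <- as.character(classify_phase(rows$cds_offset))
    out[[length(out) + 1L]] <- rows
  }
  out[[1L]] <- base[!hit_any, , drop = FALSE]
  res <- do.call(rbind, out)
  res <- res[order(res$t_coord, res$gene_id, na.last = TRUE), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Insert a transposon cargo at a TA site
#'
#' Reproduces the Himar target-site duplication: the output is
#' `seq[..through the TA] + cargo + "TA" + seq[after the TA..]`, so the output
#' is always `nchar(cargo) + 2` bases longer than the input and no base
#' outside the insertion interval changes.
#'
#' @param seq Reference sequence.
#' @param t_coord Position of the T of the target TA.
#' @param cargo A `cargo_sequence` from [build_cargo()] or a plain sequence.
#' @param orientation `"forward"` inserts the cargo as given; `"reverse"`
#'   inserts its reverse complement (an antisense event relative to a
#'   plus-strand gene).
#' @return The mutated sequence.
#' @export
apply_insertion <- function(seq, t_coord, cargo,
                            orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  seq <- as_dna(seq)
  t_coord <- as.integer(t_coord)
  if (t_coord < 1L || t_coord + 1L > nchar(seq)) {
    stop("t_coord outside sequence", call. = FALSE)
  }
  if (substr(seq, t_coord, t_coord + 1L) != "TA") {
    stop("integrity error: bases at t_coord are '",
         substr(seq, t_coord, t_coord + 1L), "', not 'TA'", call. = FALSE)
  }
  cargo_seq <- if (inherits(cargo, "cargo_sequence")) cargo$residues else
    as_dna(cargo, "cargo")
  if (orientation == "reverse") cargo_seq <- revcomp(cargo_seq)
  paste0(substr(seq, 1L, t_coord + 1L), cargo_seq, "TA",
         substr(seq, t_coord + 2L, nchar(seq)))
}

#' Excise a transposon insertion
#'
#' Exact inverse of [apply_insertion()]: removes the cargo and one TA copy, so
#' `excise_insertion(apply_insertion(s, t, cargo), t, nchar(cargo))` is `s`.
#' The TA bases flanking the stated cargo interval are verified first.
#'
#' @param seq Mutated sequence.
#' @param t_coord Position of the T of the original (upstream) TA.
#' @param cargo_len Length of the inserted cargo in bases.
#' @return The restored sequence.
#' @export
excise_insertion <- function(seq, t_coord, cargo_len) {
  seq <- as_dna(seq)
  t_coord <- as.integer(t_coord)
  cargo_len <- as.integer(cargo_len)
  dup_start <- t_coord + 2L + cargo_len
  if (t_coord < 1L || dup_start + 1L > nchar(seq)) {
    stop("integrity error: stated cargo interval exceeds sequence",
         call. = FALSE)
  }
  up <- substr(seq, t_coord, t_coord + 1L)
  down <- substr(seq, dup_start, dup_start + 1L)
  if (up != "TA" || down != "TA") {
    stop("integrity error: junctions are '", up, "'/'", down,
         "', expected TA/TA", call. = FALSE)
  }
  paste0(substr(seq, 1L, t_coord + 1L),
         substr(seq, dup_start + 2L, nchar(seq)))
}

#' Export TA sites as BED
#'
#' 0-based half-open intervals covering the TA dinucleotide; the score column
#' encodes the phase (P23 = 1, P31 = 2, P12 = 3, 0 outside a CDS).
#'
#' @param sites Data.frame from [enumerate_ta_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_sites_bed <- function(sites, path) {
  score <- c(P23 = 1L, P31 = 2L, P12 = 3L)[sites$phase]
  score[is.na(score)] <- 0L
  bed <- data.frame(
    chrom = sites$contig_id,
    start = sites$t_coord - 1L,
    end = sites$t_coord + 1L,
    name = ifelse(is.na(sites$gene_id), ".", sites$gene_id),
    score = score,
    strand = ifelse(is.na(sites$gene_strand), ".", sites$gene_strand)
  )
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Export TA sites as TSV
#'
#' One row per site/CDS pair with the compatible transposon variant.
#'
#' @inheritParams export_sites_bed
#' @return `path`, invisibly.
#' @export
export_sites_tsv <- function(sites, path) {
  sites$compatible_variant <- unname(phase_to_variant(sites$phase))
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
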