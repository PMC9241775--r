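# Exact-match mapping of short junction tags (Tn tags) to insertion sites.
#
# A Tn tag is the short junction sequence read outward from an insertion: it
# begins with the target TA and continues into the adjacent reference bases on
# the insertion's reading strand. Because the tag is exact Sanger-derived
# sequence, mapping is exact string matching on both strands; ambiguity
# (multiple genomic matches) is surfaced, never resolved.

#' Construct and validate a Tn tag
#'
#' @param residues Tag sequence; must begin with `TA` and be 8-12 bases long
#'   (printed tags are typically 10 characters: the TA plus the adjacent
#'   bases).
#' @param label Tag label (e.g. a strain identifier).
#' @return An object of class `tn_tag`.
#' @export
tn_tag <- function(residues, label = "tag") {
  residues <- as_dna(residues, "tag")
  if (!startsWith(residues, "TA")) {
    stop("tag must begin with the target-site TA: got '",
         substr(residues, 1, 2), "'", call. = FALSE)
  }
  if (nchar(residues) < 8L || nchar(residues) > 12L) {
    stop("tag length must be 8-12 bases, got ", nchar(residues),
         call. = FALSE)
  }
  structure(list(label = label, residues = residues), class = "tn_tag")
}

#' Extract the Tn tag of an insertion site
#'
#' Reads `TA` plus `length - 2` downstream reference bases on the insertion's
#' reading strand. The 8-12 base bound of [tn_tag()] applies to externally
#' supplied tags; extraction permits any length >= 2 (a length-2 read is just
#' the TA itself).
#'
#' @param seq Reference sequence.
#' @param t_coord Position of the T of the target TA (forward strand).
#' @param length Total tag length (default 10).
#' @param strand Reading strand of the insertion (`"+"` or `"-"`).
#' @param label Tag label.
#' @return A [tn_tag()].
#' @export
extract_tag <- function(seq, t_coord, length = 10L, strand = "+",
                        label = "tag") {
  seq <- as_dna(seq)
  t_coord <- as.integer(t_coord)
  length <- as.integer(length)
  if (length < 2L) stop("tag length must be at least 2", call. = FALSE)
  if (substr(seq, t_coord, t_coord + 1L) != "TA") {
    stop("integrity error: no TA at t_coord ", t_coord, call. = FALSE)
  }
  if (strand == "+") {
    if (t_coord + length - 1L > nchar(seq)) {
      stop("site too close to sequence end for a ", length, "-base tag",
           call. = FALSE)
    }
    residues <- substr(seq, t_coord, t_coord + length - 1L)
  } else {
    if (t_coord + 2L - length < 1L) {
      stop("site too close to sequence start for a ", length, "-base tag",
           call. = FALSE)
    }
    residues <- revcomp(substr(seq, t_coord + 2L - length, t_coord + 1L))
  }
  structure(list(label = label, residues = residues), class = "tn_tag")
}

#' Map a Tn tag to insertion sites in a genome
#'
#' Exact-match search on both strands of every contig. A forward-strand match
#' anchors the insertion at the match start; a reverse-strand match anchors it
#' so that the tag's leading TA sits on the reverse reading strand (forward
#' coordinates `(end - 1, end)` of the reverse-complemented match). Hits are
#' annotated with CDS overlap, `cds_offset`, phase and the compatible variant
#' when annotations are supplied.
#'
#' @param tag A [tn_tag()] or a tag sequence string.
#' @param genome Named character vector of contig sequences.
#' @param annotations Optional CDS data.frame as from [read_gff_cds()].
#' @return A data.frame of hits: `tag_label`, `contig_id`, `t_coord`,
#'   `strand`, `gene_id`, `cds_offset`, `phase`, `compatible_variant`,
#'   `n_hits_total`, `ambiguous`. Zero hits yield an empty frame with a
#'   warning.
#' @export
map_tag <- function(tag, genome, annotations = NULL) {
  if (!inherits(tag, "tn_tag")) tag <- tn_tag(tag)
  if (is.null(names(genome))) names(genome) <- "seq"
  hits <- list()
  for (contig in names(genome)) {
    subject <- Biostrings::DNAString(genome[[contig]])
    fwd <- Biostrings::start(Biostrings::matchPattern(tag$residues, subject))
    rev_m <- Biostrings::matchPattern(revcomp(tag$residues), subject)
    rev_end <- Biostrings::end(rev_m)
    if (length(fwd)) {
      hits[[length(hits) + 1L]] <- data.frame(
        contig_id = contig, t_coord = as.integer(fwd), strand = "+",
        stringsAsFactors = FALSE
      )
    }
    if (length(rev_end)) {
      hits[[length(hits) + 1L]] <- data.frame(
        contig_id = contig, t_coord = as.integer(rev_end) - 1L, strand = "-",
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(hits) == 0L) {
    warning("tag ", tag$label, " not found in the reference", call. = FALSE)
    return(data.frame(
      tag_label = character(0), contig_id = character(0),
      t_coord = integer(0), strand = character(0), gene_id = character(0),
      cds_offset = integer(0), phase = character(0),
      compatible_variant = character(0), n_hits_total = integer(0),
      ambiguous = logical(0), stringsAsFactors = FALSE
    ))
  }
  hits <- do.call(rbind, hits)
  n <- nrow(hits)
  hits$tag_label <- tag$label
  hits$gene_id <- NA_character_
  hits$cds_offset <- NA_integer_
  hits$phase <- NA_character_
  if (!is.null(annotations) && nrow(annotations)) {
    ann <- annotations
    if ("partial" %in% names(ann)) ann <- ann[!ann$partial, , drop = FALSE]
    for (i in seq_len(n)) {
      if ("contig_id" %in% names(ann)) {
        cand <- ann[ann$contig_id == hits$contig_id[i], , drop = FALSE]
      } else {
        cand <- ann
      }
      j <- which(cand$start <= hits$t_coord[i] &
                   cand$end >= hits$t_coord[i] + 1L)
      if (length(j)) {
        j <- j[1L]
        hits$gene_id[i] <- cand$gene_id[j]
        hits$cds_offset[i] <- as.integer(cds_offset_for_site(
          hits$t_coord[i], cand$start[j], cand$end[j], cand$strand[j]
        ))
        hits$phase[i] <- as.character(classify_phase(hits$cds_offset[i]))
      }
    }
  }
  hits$compatible_variant <- unname(phase_to_variant(hits$phase))
  hits$n_hits_total <- n
  hits$ambiguous <- n > 1L
  hits[, c("tag_label", "contig_id", "t_coord", "strand", "gene_id",
           "cds_offset", "phase", "compatible_variant", "n_hits_total",
           "ambiguous")]
}

#' Map a batch of Tn tags
#'
#' @param tags A data.frame with columns `label` and `tag`, a named character
#'   vector, or a list of [tn_tag()] objects.
#' @param genome Named character vector of contig sequences.
#' @param annotations Optional CDS data.frame.
#' @return List with `hits` (one row per (tag, hit)) and `summary` (list:
#'   `n_tags`, `n_mapped`, `n_unmapped`, `n_ambiguous`, `n_unique_loci`).
#' @export
batch_map <- function(tags, genome, annotations = NULL) {
  tag_list <- if (is.data.frame(tags)) {
    lapply(seq_len(nrow(tags)), function(i) tn_tag(tags$tag[i], tags$label[i]))
  } else if (is.character(tags)) {
    labels <- names(tags) %||% paste0("tag", seq_along(tags))
    lapply(seq_along(tags), function(i) tn_tag(tags[[i]], labels[i]))
  } else {
    tags
  }
  per_tag <- lapply(tag_list, function(tg) {
    suppressWarnings(map_tag(tg, genome, annotations))
  })
  hits <- if (length(per_tag)) do.call(rbind, per_tag) else
    data.frame(
      tag_label = character(0), contig_id = character(0),
      t_coord = integer(0), strand = character(0), gene_id = character(0),
      cds_offset = integer(0), phase = character(0),
      compatible_variant = character(0), n_hits_total = integer(0),
      ambiguous = logical(0), stringsAsFactors = FALSE
    )
  mapped <- vapply(per_tag, nrow, integer(1)) > 0L
  ambiguous <- vapply(per_tag, function(h) any(h$ambiguous), logical(1))
  loci <- unique(hits[, c("contig_id", "t_coord", "strand"), drop = FALSE])
  list(
    hits = hits,
    summary = list(
      n_tags = length(tag_list),
      n_mapped = sum(mapped),
      n_unmapped = sum(!mapped),
      n_ambiguous = sum(ambiguous & mapped),
      n_unique_loci = nrow(loci)
    )
  )
}

#' Read a Tn tag list from a file
#'
#' Accepts either one tag per line or a two-column TSV (`label`, `tag`), with
#' or without a header line.
#'
#' @param path Input path.
#' @return A data.frame with columns `label` and `tag`.
#' @export
read_tags <- function(path) {
  if (!file.exists(path)) stop("tag file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) {
    return(data.frame(label = character(0), tag = character(0)))
  }
  parts <- strsplit(lines, "\t")
  two_col <- all(vapply(parts, length, integer(1)) >= 2L)
  if (two_col) {
    df <- data.frame(
      label = vapply(parts, `[[`, character(1), 1L),
      tag = toupper(vapply(parts, `[[`, character(1), 2L)),
      stringsAsFactors = FALSE
    )
    if (grepl("[^ACGTN]", df$tag[1L])) df <- df[-1L, , drop = FALSE]  # header
  } else {
    tagseq <- toupper(trimws(lines))
    df <- data.frame(label = paste0("tag", seq_along(tagseq)), tag = tagseq,
                     stringsAsFactors = FALSE)
  }
  df
}
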