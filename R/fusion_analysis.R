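# Reading-frame verification through an insertion and fusion protein
# prediction.
#
# A (site, variant) pair is "productive" when the event is cooriented with
# the target, the site's codon phase matches the variant's compatible phase,
# and translation through the whole cargo (upstream ITR, spacers, reporter,
# downstream ITR, duplicated TA) reaches the natural target stop without a
# premature stop codon.

#' Verify reading-frame continuity of a (mutated) CDS
#'
#' Translates from `cds_start` in frame 0 with full-frame scan semantics and
#' reports whether the first stop codon appears only after `expected_len`
#' residues.
#'
#' @param mutated Nucleotide sequence containing the CDS.
#' @param cds_start 1-based position of the ATG.
#' @param expected_len Number of amino acids expected before the natural stop.
#' @return List with `continuous` (logical) and `first_stop` (residue index of
#'   the first stop codon, NA if none).
#' @export
verify_orf <- function(mutated, cds_start, expected_len) {
  mutated <- as_dna(mutated)
  cds_start <- as.integer(cds_start)
  if (substr(mutated, cds_start, cds_start + 2L) != "ATG") {
    stop("no ATG at cds_start ", cds_start, call. = FALSE)
  }
  aa <- translate_dna(substr(mutated, cds_start, nchar(mutated)))
  first_stop <- regexpr("*", aa, fixed = TRUE)
  first_stop <- if (first_stop == -1L) NA_integer_ else as.integer(first_stop)
  list(
    continuous = is.na(first_stop) || first_stop > expected_len,
    first_stop = first_stop
  )
}

# Residue-level segment labels from a nucleotide-level segment tiling: each
# codon is labelled by the segment holding its first base; the duplicated TA
# and the 3' spacer are folded into the downstream linker, the 5' spacer is
# reported as "spacer".
residue_segments <- function(nt_labels, n_res) {
  fold <- c(
    target_N = "target_N", itr_up = "itr_up_linker", spacer5 = "spacer",
    reporter = "reporter", spacer3 = "itr_down_linker",
    itr_down = "itr_down_linker", ta_dup = "itr_down_linker",
    gap = "itr_down_linker", target_C = "target_C"
  )
  first_base <- nt_labels[(seq_len(n_res) - 1L) * 3L + 1L]
  lab <- unname(fold[first_base])
  runs <- rle(lab)
  end <- cumsum(runs$lengths)
  data.frame(
    segment = runs$values,
    start = end - runs$lengths + 1L,
    end = end,
    stringsAsFactors = FALSE
  )
}

#' Predict the fusion protein produced by a transposon insertion
#'
#' Constructs the post-insertion gene, translates it, and segments the
#' predicted protein into target, linker and reporter parts. Two topologies
#' are supported:
#' * internal (`cds_offset > 0`): a sandwich fusion
#'   target-N / ITR linker / reporter / ITR linker / target-C;
#' * N-terminal (`cds_offset < 0`, insertion upstream of the ATG): the fusion
#'   reads reporter-first through the downstream ITR, the duplicated TA and
#'   any intervening upstream bases into the intact target, and is productive
#'   only when that path is in frame and stop-free.
#'
#' Antisense events are rejected: the reverse-complemented reporter has no
#' defined reading frame into the target.
#'
#' @param gene Nucleotide sequence containing the CDS (and any upstream
#'   context).
#' @param t_coord Position of the T of the target TA within `gene`.
#' @param variant The [transposon_variant()] inserted.
#' @param cds_start,cds_end CDS bounds within `gene` (default: the whole
#'   sequence).
#' @param orientation Must be `"coorient"`.
#' @param gene_id Label carried into the result.
#' @return An object of class `fusion_construct`: list with `gene_id`,
#'   `t_coord`, `cds_offset`, `phase`, `variant_name`, `topology`, `mutated`
#'   (full mutated sequence), `protein` (residues up to, excluding, the first
#'   stop), `expected_len`, `premature_stop` (residue index or NA),
#'   `productive`, `segments` (residue segment map) and `nt_segments`
#'   (nucleotide segment map of the fusion ORF).
#' @export
predict_fusion_protein <- function(gene, t_coord, variant,
                                   cds_start = 1L, cds_end = nchar(gene),
                                   orientation = "coorient",
                                   gene_id = "gene") {
  if (!identical(orientation, "coorient")) {
    stop("antisense events do not produce fusions: the reverse-complemented ",
         "reporter has no reading frame into the target", call. = FALSE)
  }
  gene <- as_dna(gene)
  t_coord <- as.integer(t_coord)
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  if ((cds_end - cds_start + 1L) %% 3L != 0L) {
    stop("CDS length is not a multiple of 3", call. = FALSE)
  }
  cargo <- build_cargo(variant)
  seg_seqs <- setNames(
    substring(cargo$residues, cargo$segment_map$start, cargo$segment_map$end),
    cargo$segment_map$segment
  )
  mutated <- apply_insertion(gene, t_coord, cargo, orientation = "forward")
  cds_offset <- if (t_coord >= cds_start) t_coord - cds_start + 1L else
    t_coord - cds_start
  phase <- as.character(classify_phase(cds_offset))
  wt_res <- (cds_end - cds_start + 1L) %/% 3L - 1L
  cargo_res_extra <- (nchar(cargo$residues) + 2L) %/% 3L

  if (cds_offset > 0L) {
    if (t_coord + 1L > cds_end) {
      stop("site not within the CDS", call. = FALSE)
    }
    pieces <- c(
      target_N = substr(gene, cds_start, t_coord + 1L),
      seg_seqs,
      ta_dup = "TA",
      target_C = substr(gene, t_coord + 2L, cds_end)
    )
    topology <- "internal"
    orf_start_in_mutated <- cds_start
  } else {
    if (t_coord + 1L >= cds_start) {
      stop("site straddles the start codon", call. = FALSE)
    }
    # reporter-first ORF: reporter, 3' spacer, downstream ITR, duplicated TA,
    # upstream gap bases, then the intact target CDS
    pieces <- c(
      seg_seqs[c("reporter", "spacer3", "itr_down")],
      ta_dup = "TA",
      gap = substr(gene, t_coord + 2L, cds_start - 1L),
      target_C = substr(gene, cds_start, cds_end)
    )
    names(pieces)[1:3] <- c("reporter", "spacer3", "itr_down")
    topology <- "n_terminal"
    # reporter begins after itr_up + spacer5 within the inserted cargo
    orf_start_in_mutated <- t_coord + 2L + nchar(seg_seqs[["itr_up"]]) +
      nchar(seg_seqs[["spacer5"]])
  }

  orf <- paste(pieces, collapse = "")
  nt_labels <- rep(names(pieces), times = nchar(pieces))
  in_frame <- nchar(orf) %% 3L == 0L
  expected_len <- if (topology == "internal") wt_res + cargo_res_extra else
    nchar(orf) %/% 3L - 1L
  aa_full <- translate_dna(orf)
  first_stop <- regexpr("*", aa_full, fixed = TRUE)
  first_stop <- if (first_stop == -1L) NA_integer_ else as.integer(first_stop)
  premature <- if (!in_frame) {
    first_stop %||% NA_integer_
  } else if (!is.na(first_stop) && first_stop <= expected_len) first_stop else
    NA_integer_
  protein <- if (is.na(first_stop)) aa_full else
    substr(aa_full, 1L, first_stop - 1L)
  productive <- in_frame && is.na(premature) &&
    identical(phase, variant$compatible_phase) &&
    (topology == "internal" || !is.na(first_stop))
  segments <- residue_segments(nt_labels, nchar(protein))
  nt_end <- cumsum(nchar(pieces))
  structure(list(
    gene_id = gene_id,
    t_coord = t_coord,
    cds_offset = cds_offset,
    phase = phase,
    variant_name = variant$name,
    topology = topology,
    mutated = mutated,
    orf_start = orf_start_in_mutated,
    protein = protein,
    expected_len = expected_len,
    premature_stop = premature,
    productive = productive,
    segments = segments,
    nt_segments = data.frame(
      segment = names(pieces),
      start = as.integer(nt_end - nchar(pieces) + 1L),
      end = as.integer(nt_end),
      stringsAsFactors = FALSE
    )
  ), class = "fusion_construct")
}

#' @export
print.fusion_construct <- function(x, ...) {
  cat(sprintf(
    "<fusion_construct %s> %s insertion at offset %d (%s) by %s: %s, %d aa%s\n",
    x$gene_id, x$topology, x$cds_offset, x$phase, x$variant_name,
    if (x$productive) "productive" else "nonproductive", nchar(x$protein),
    if (is.na(x$premature_stop)) "" else
      sprintf(", premature stop at residue %d", x$premature_stop)
  ))
  invisible(x)
}

#' Scan one gene for productive insertion sites
#'
#' Enumerates every in-CDS TA site and reports, for each site and each
#' variant, whether the variant's compatible phase matches the site, and for
#' the matching variant whether full translation through the construct is
#' stop-free (`premature_stop`).
#'
#' @param gene Nucleotide sequence containing the CDS.
#' @param variants List of [transposon_variant()] objects.
#' @param cds_start,cds_end CDS bounds (default: the whole sequence).
#' @param gene_id Gene label.
#' @return A data.frame with one row per (site, variant) pair: `gene_id`,
#'   `t_coord`, `cds_offset`, `phase`, `variant`, `compatible`, `productive`,
#'   `premature_stop`. A partial CDS yields zero rows with a warning.
#' @export
scan_gene <- function(gene, variants, cds_start = 1L, cds_end = nchar(gene),
                      gene_id = "gene") {
  gene <- as_dna(gene)
  empty <- data.frame(
    gene_id = character(0), t_coord = integer(0), cds_offset = integer(0),
    phase = character(0), variant = character(0), compatible = logical(0),
    productive = logical(0), premature_stop = integer(0),
    stringsAsFactors = FALSE
  )
  if ((cds_end - cds_start + 1L) %% 3L != 0L) {
    warning("partial CDS for ", gene_id, ": skipped", call. = FALSE)
    return(empty)
  }
  ann <- data.frame(gene_id = gene_id, start = cds_start, end = cds_end,
                    strand = "+", stringsAsFactors = FALSE)
  sites <- enumerate_ta_sites(gene, ann, contig_id = "contig")
  sites <- sites[sites$in_cds, , drop = FALSE]
  if (nrow(sites) == 0L) return(empty)
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    do.call(rbind, lapply(variants, function(v) {
      compatible <- identical(v$compatible_phase, sites$phase[i])
      premature <- NA_integer_
      productive <- FALSE
      if (compatible) {
        fus <- predict_fusion_protein(
          gene, sites$t_coord[i], v, cds_start = cds_start,
          cds_end = cds_end, gene_id = gene_id
        )
        premature <- fus$premature_stop
        productive <- fus$productive
      }
      data.frame(
        gene_id = gene_id, t_coord = sites$t_coord[i],
        cds_offset = sites$cds_offset[i], phase = sites$phase[i],
        variant = v$name, compatible = compatible, productive = productive,
        premature_stop = premature, stringsAsFactors = FALSE
      )
    }))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Scan a genome for productive insertion sites
#'
#' Runs [scan_gene()] over every complete CDS of every contig and aggregates
#' genome-level phase statistics.
#'
#' @param genome Named character vector of contig sequences.
#' @param annotations CDS data.frame as from [read_gff_cds()].
#' @param variants List of [transposon_variant()] objects.
#' @return An object of class `scan_report`: list with `rows` (the
#'   concatenated [scan_gene()] tables) and `summary` (list with
#'   `n_sites`, `per_phase`, `per_gene`, `n_productive`).
#' @export
scan_genome <- function(genome, annotations, variants) {
  stopifnot(!is.null(names(genome)))
  keep <- if ("partial" %in% names(annotations)) !annotations$partial else
    rep(TRUE, nrow(annotations))
  ann <- annotations[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    contig <- genome[[ann$contig_id[i]]]
    if (is.null(contig)) {
      stop("annotation refers to unknown contig ", ann$contig_id[i],
           call. = FALSE)
    }
    if (identical(ann$strand[i], "-")) {
      # scan on the reading strand; coordinates reported in CDS space
      gene <- revcomp(substr(contig, ann$start[i], ann$end[i]))
      scan_gene(gene, variants, gene_id = ann$gene_id[i])
    } else {
      scan_gene(contig, variants, cds_start = ann$start[i],
                cds_end = ann$end[i], gene_id = ann$gene_id[i])
    }
  })
  rows <- do.call(rbind, rows)
  per_site <- unique(rows[, c("gene_id", "t_coord", "phase")])
  structure(list(
    rows = rows,
    summary = list(
      n_sites = nrow(per_site),
      per_phase = table(factor(per_site$phase, levels = PHASES)),
      per_gene = table(per_site$gene_id),
      n_productive = sum(rows$productive)
    )
  ), class = "scan_report")
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf(
    "<scan_report> %d in-CDS TA sites across %d gene(s); %d productive (site, variant) pairs\n",
    x$summary$n_sites, length(x$summary$per_gene), x$summary$n_productive
  ))
  print(x$summary$per_phase)
  invisible(x)
}

#' Deduplicate candidate insertions
#'
#' Unique by key columns (default `gene_id` + `cds_offset`), keeping the first
#' occurrence in input order — the bookkeeping used when sequencing a pool of
#' enriched candidates recovers the same insertion in several sibling
#' isolates.
#'
#' @param rows Data.frame of candidates.
#' @param keys Character vector of key columns.
#' @return The deduplicated data.frame, original order preserved.
#' @export
dedup_candidates <- function(rows, keys = c("gene_id", "cds_offset")) {
  if (nrow(rows) == 0L) return(rows)
  stopifnot(all(keys %in% names(rows)))
  out <- rows[!duplicated(rows[, keys, drop = FALSE]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a scan report as GFF3
#'
#' One feature per productive (site, variant) row, with the variant and phase
#' as attributes.
#'
#' @param report A `scan_report` from [scan_genome()].
#' @param path Output path.
#' @param contig_id Contig name for the features.
#' @return `path`, invisibly.
#' @export
export_scan_gff3 <- function(report, path, contig_id = "seq") {
  rows <- report$rows[report$rows$productive, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = rep(contig_id, nrow(rows)),
    ranges = IRanges::IRanges(start = rows$t_coord, end = rows$t_coord + 1L),
    strand = "+"
  )
  gr$type <- "insertion_site"
  gr$ID <- sprintf("%s_%d_%s", rows$gene_id, rows$cds_offset, rows$variant)
  gr$variant <- rows$variant
  gr$phase_class <- rows$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
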