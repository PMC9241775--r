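# Split-fluorophore construct design for bimolecular fluorescence
# complementation (BiFC): a bait protein fused to the N-terminal fragment of
# the fluorophore, and a transposon prey delivering the C-terminal fragment.
# The default split follows the mVenus design: split after residue 154, i.e.
# a 462-bp N fragment and a 255-bp (85-residue) C fragment of a 717-bp CDS.

#' Split a fluorophore coding sequence into BiFC fragments
#'
#' @param cds Fluorophore CDS with the stop codon excluded; length a multiple
#'   of 3 and free of stop codons in frame 0.
#' @param split_residue Last residue of the N-terminal fragment (default 154).
#' @return An object of class `split_fluorophore`: list with `full_cds`,
#'   `split_residue`, `frag_n_cds`, `frag_c_cds`, `n_len_bp`, `c_len_bp`,
#'   `n_len_aa`, `c_len_aa`. The fragments concatenate exactly to the input.
#' @export
split_fluorophore <- function(cds, split_residue = 154L) {
  cds <- as_dna(cds, "fluorophore CDS")
  split_residue <- as.integer(split_residue)
  if (nchar(cds) %% 3L != 0L) {
    stop("fluorophore CDS length must be a multiple of 3", call. = FALSE)
  }
  n_res <- nchar(cds) %/% 3L
  aa <- translate_dna(cds)
  if (grepl("*", aa, fixed = TRUE)) {
    stop("fluorophore CDS contains a stop codon at residue ",
         regexpr("*", aa, fixed = TRUE),
         " (supply the CDS with the stop codon excluded)", call. = FALSE)
  }
  if (split_residue <= 0L || split_residue >= n_res) {
    stop("split_residue must lie strictly inside the protein (1..",
         n_res - 1L, ")", call. = FALSE)
  }
  structure(list(
    full_cds = cds,
    split_residue = split_residue,
    frag_n_cds = substr(cds, 1L, 3L * split_residue),
    frag_c_cds = substr(cds, 3L * split_residue + 1L, nchar(cds)),
    n_len_bp = 3L * split_residue,
    c_len_bp = nchar(cds) - 3L * split_residue,
    n_len_aa = split_residue,
    c_len_aa = n_res - split_residue
  ), class = "split_fluorophore")
}

#' @export
print.split_fluorophore <- function(x, ...) {
  cat(sprintf(
    "<split_fluorophore> split after residue %d: N fragment %d bp (%d aa), C fragment %d bp (%d aa)\n",
    x$split_residue, x$n_len_bp, x$n_len_aa, x$c_len_bp, x$c_len_aa
  ))
  invisible(x)
}

#' Build a BiFC bait construct
#'
#' Fuses the target CDS (terminal stop stripped if present) through an
#' optional in-frame linker to the N-terminal fluorophore fragment, appends a
#' stop codon, and validates the construct by translation.
#'
#' @param target_cds Target coding sequence.
#' @param split A [split_fluorophore()].
#' @param linker Linker bases between target and fragment; length must be a
#'   multiple of 3.
#' @return An object of class `bait_construct`: list with `seq`, `protein`,
#'   and `segments` (nucleotide segment map: target, linker, frag_n, stop).
#' @export
build_bait <- function(target_cds, split, linker = "") {
  stopifnot(inherits(split, "split_fluorophore"))
  target_cds <- as_dna(target_cds, "target CDS")
  linker <- as_dna(linker, "linker")
  if (nchar(target_cds) %% 3L != 0L) {
    stop("target CDS length must be a multiple of 3", call. = FALSE)
  }
  if (nchar(linker) %% 3L != 0L) {
    stop("frame error: linker length ", nchar(linker),
         " is not a multiple of 3", call. = FALSE)
  }
  target_aa <- translate_dna(target_cds)
  if (substr(target_aa, nchar(target_aa), nchar(target_aa)) == "*") {
    target_cds <- substr(target_cds, 1L, nchar(target_cds) - 3L)
    target_aa <- substr(target_aa, 1L, nchar(target_aa) - 1L)
  }
  stop_at <- regexpr("*", target_aa, fixed = TRUE)
  if (stop_at != -1L) {
    stop("target CDS has an internal stop codon at residue ", stop_at,
         call. = FALSE)
  }
  parts <- c(target = target_cds, linker = linker,
             frag_n = split$frag_n_cds, stop = "TAA")
  seqc <- paste(parts, collapse = "")
  aa <- translate_dna(seqc)
  internal <- regexpr("*", substr(aa, 1L, nchar(aa) - 1L), fixed = TRUE)
  if (internal != -1L) {
    stop("bait construct has an internal stop codon at residue ", internal,
         call. = FALSE)
  }
  nt_end <- cumsum(nchar(parts))
  structure(list(
    seq = seqc,
    protein = substr(aa, 1L, nchar(aa) - 1L),
    segments = data.frame(
      segment = names(parts),
      start = as.integer(nt_end - nchar(parts) + 1L),
      end = as.integer(nt_end),
      stringsAsFactors = FALSE
    )
  ), class = "bait_construct")
}

#' Build a BiFC prey transposon
#'
#' A transposon variant whose reporter is the C-terminal fluorophore fragment.
#' Only the two architectures shown to transpose (`open1`, `open2`) are
#' built by default; `open3` (nonfunctional in vivo due to the required ITR
#' modifications) is refused unless `allow_open3 = TRUE`.
#'
#' @param variant_name `"open1"` or `"open2"` (or `"open3"` with
#'   `allow_open3`).
#' @param split A [split_fluorophore()].
#' @param allow_open3 Override the open3 refusal.
#' @param ... Passed to [transposon_variant()] (e.g. custom ITRs).
#' @return A validated [transposon_variant()] carrying the C fragment.
#' @export
build_prey_transposon <- function(variant_name, split, allow_open3 = FALSE,
                                  ...) {
  stopifnot(inherits(split, "split_fluorophore"))
  if (identical(variant_name, "open3") && !allow_open3) {
    stop("open3 prey refused: the open3 architecture did not transpose ",
         "functionally in vivo; pass allow_open3 = TRUE to build it anyway",
         call. = FALSE)
  }
  v <- transposon_variant(variant_name, reporter = split$frag_c_cds,
                          reporter_name = sprintf("fluorophore C fragment (%d aa)",
                                                  split$c_len_aa),
                          ...)
  report <- validate_variant(v)
  if (!attr(report, "valid")) {
    stop("prey reporter fragment violates variant invariants: ",
         paste(report$rule[!report$pass], collapse = ", "), call. = FALSE)
  }
  v
}

#' Report the segment topology of a prey insertion into the bait
#'
#' For an insertion landing inside the bait construct, reports the order of
#' bait segments and the delivered C fragment in the resulting primary
#' sequence: the containing bait segment is split into `_N`/`_C` parts around
#' the prey reporter. An insertion within the bait's target region yields
#' `target_N, fragC, target_C, frag_n` — the two fluorophore fragments in
#' reversed order, the hallmark of a bait self-insertion.
#'
#' @param bait A [build_bait()] construct.
#' @param t_coord Position of the target TA within the bait sequence.
#' @return List with `within_bait`, `insertion_segment`, and `topology`
#'   (character vector of segment labels in primary-sequence order).
#' @export
detect_self_insertion <- function(bait, t_coord) {
  stopifnot(inherits(bait, "bait_construct"))
  t_coord <- as.integer(t_coord)
  seg <- bait$segments
  coding <- seg[seg$segment != "stop", , drop = FALSE]
  j <- which(coding$start <= t_coord & coding$end >= t_coord + 1L)
  if (length(j) == 0L) {
    return(list(within_bait = FALSE, insertion_segment = NA_character_,
                topology = character(0)))
  }
  j <- j[1L]
  keep <- coding$segment[nchar(substring(bait$seq, coding$start,
                                         coding$end)) > 0L]
  before <- keep[seq_along(keep) < match(coding$segment[j], keep)]
  after <- keep[seq_along(keep) > match(coding$segment[j], keep)]
  topology <- c(before, paste0(coding$segment[j], "_N"), "fragC",
                paste0(coding$segment[j], "_C"), after)
  list(
    within_bait = TRUE,
    insertion_segment = coding$segment[j],
    topology = topology
  )
}
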