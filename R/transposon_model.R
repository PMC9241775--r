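# The three reading-frame-preserving transposon architectures.
#
# Each architecture carries a stop-free reporter between two 27-bp Himar ITRs,
# padded by spacers whose lengths make the whole cargo plus the 2-bp TA
# target-site duplication a multiple of 3:
#   open1: 0-bp 5' spacer, 1-bp 3' spacer, compatible with P23 sites
#   open2: 2-bp 5' spacer, 2-bp 3' spacer, compatible with P31 sites
#   open3: 1-bp 5' spacer, 3-bp 3' spacer, compatible with P12 sites

#' Canonical 27-bp Himar1 mariner inverted terminal repeat
#'
#' Default ITR used when a variant does not configure its own. Any configured
#' ITR is validated with [scan_itr_stops()] rather than assumed stop-free.
#' @export
HIMAR_ITR <- "ACAGGTTGGCTGATAAGTCCCCGGTCT"

PHASES <- c("P23", "P31", "P12")

# Spacer lengths are fixed by the architecture (0/1, 2/2, 1/3); the base
# identities are configurable defaults chosen so that no stop codon forms at
# the spacer junctions of the default ITR pair (e.g. the canonical upstream
# ITR ends in T, so a 5' spacer starting A or AG would create TGA/TAG for
# open2's entry frame).
VARIANT_SPACERS <- list(
  open1 = list(spacer5 = "",   spacer3 = "A",   phase = "P23"),
  open2 = list(spacer5 = "GG", spacer3 = "AG",  phase = "P31"),
  open3 = list(spacer5 = "G",  spacer3 = "GGA", phase = "P12")
)

#' Map a codon phase to the compatible transposon variant name
#'
#' @param phase Character vector of phase labels (`P23`, `P31`, `P12`).
#' @return Variant names (`open1`, `open2`, `open3`); NA for other input.
#' @export
phase_to_variant <- function(phase) {
  c(P23 = "open1", P31 = "open2", P12 = "open3")[as.character(phase)]
}

#' Construct a transposon variant
#'
#' A variant bundles the two ITRs, the 5'/3' spacers and the reporter
#' cassette. For the stock names `open1`/`open2`/`open3` the spacers default
#' to the architecture's defined lengths; custom spacers are accepted but
#' [validate_variant()] will report any deviation from the named
#' architecture's spacer lengths and any frame imbalance.
#'
#' @param name Variant name, normally one of `"open1"`, `"open2"`, `"open3"`.
#' @param reporter Reporter coding sequence: length a multiple of 3, no stop
#'   codon in frame 0, and no terminal stop codon (translation must read
#'   through the transposon).
#' @param reporter_name Label for the reporter (e.g. `"mNeongreen"`).
#' @param itr_up,itr_down Upstream/downstream ITR sequences in cargo
#'   orientation. Defaults: the canonical 27-bp Himar1 ITR upstream and — the
#'   repeats being inverted — its reverse complement downstream.
#' @param spacer5,spacer3 Spacer sequences; NULL means the stock spacer for
#'   `name`.
#' @param compatible_phase Phase preserved by this architecture; NULL means
#'   the stock phase for `name`.
#' @return An object of class `transposon_variant`.
#' @export
transposon_variant <- function(name, reporter, reporter_name = "reporter",
                               itr_up = HIMAR_ITR, itr_down = NULL,
                               spacer5 = NULL, spacer3 = NULL,
                               compatible_phase = NULL) {
  if (is.null(itr_down)) itr_down <- revcomp(itr_up)
  stock <- VARIANT_SPACERS[[name]]
  if (is.null(stock) && (is.null(spacer5) || is.null(spacer3) ||
                         is.null(compatible_phase))) {
    stop("unknown variant name '", name,
         "': spacers and compatible_phase must be given explicitly",
         call. = FALSE)
  }
  v <- structure(list(
    name = name,
    itr_up = as_dna(itr_up, "itr_up"),
    itr_down = as_dna(itr_down, "itr_down"),
    spacer5 = as_dna(spacer5 %||% stock$spacer5, "spacer5"),
    spacer3 = as_dna(spacer3 %||% stock$spacer3, "spacer3"),
    reporter = as_dna(reporter, "reporter"),
    reporter_name = reporter_name,
    compatible_phase = compatible_phase %||% stock$phase
  ), class = "transposon_variant")
  v
}

#' @export
print.transposon_variant <- function(x, ...) {
  cat(sprintf(
    "<transposon_variant %s> ITRs %d/%d bp, spacers %d/%d bp, reporter %s (%d bp), phase %s\n",
    x$name, nchar(x$itr_up), nchar(x$itr_down), nchar(x$spacer5),
    nchar(x$spacer3), x$reporter_name, nchar(x$reporter), x$compatible_phase
  ))
  invisible(x)
}

#' Validate a transposon variant
#'
#' Checks, rule by rule:
#' * reporter length is a multiple of 3;
#' * reporter has no internal stop codon in frame 0;
#' * reporter does not end in a stop codon;
#' * spacer lengths match the named architecture (0/1, 2/2, 1/3);
#' * frame balance: `(|itr_up| + |spacer5| + |reporter| + |spacer3| +
#'   |itr_down| + 2) mod 3 == 0`, the `+2` being the TA duplication.
#'
#' @param variant A [transposon_variant()].
#' @return A data.frame with columns `rule`, `pass`, `detail`; attribute
#'   `valid` is TRUE iff all rules pass.
#' @export
validate_variant <- function(variant) {
  stopifnot(inherits(variant, "transposon_variant"))
  rules <- list()
  add <- function(rule, pass, detail = "") {
    rules[[length(rules) + 1L]] <<- data.frame(
      rule = rule, pass = pass, detail = detail, stringsAsFactors = FALSE
    )
  }
  rep_len_ok <- nchar(variant$reporter) %% 3L == 0L
  add("reporter_length_multiple_of_3", rep_len_ok,
      sprintf("%d bp", nchar(variant$reporter)))
  aa <- if (rep_len_ok) translate_dna(variant$reporter) else ""
  internal_stop <- rep_len_ok && nchar(aa) > 1L &&
    grepl("\\*", substr(aa, 1L, nchar(aa) - 1L))
  add("reporter_no_internal_stop", !internal_stop,
      if (internal_stop) {
        sprintf("stop at codon %d", regexpr("\\*", aa))
      } else ""
  )
  ends_stop <- rep_len_ok && nchar(aa) > 0L &&
    substr(aa, nchar(aa), nchar(aa)) == "*"
  add("reporter_no_terminal_stop", !ends_stop,
      if (ends_stop) "reporter must read through into the 3' spacer" else "")
  stock <- VARIANT_SPACERS[[variant$name]]
  if (!is.null(stock)) {
    ok5 <- nchar(variant$spacer5) == nchar(stock$spacer5)
    ok3 <- nchar(variant$spacer3) == nchar(stock$spacer3)
    add("spacer_lengths_for_variant", ok5 && ok3,
        sprintf("got %d/%d, %s defines %d/%d",
                nchar(variant$spacer5), nchar(variant$spacer3), variant$name,
                nchar(stock$spacer5), nchar(stock$spacer3)))
  }
  tot <- nchar(variant$itr_up) + nchar(variant$spacer5) +
    nchar(variant$reporter) + nchar(variant$spacer3) +
    nchar(variant$itr_down) + 2L
  add("frame_balance", tot %% 3L == 0L,
      sprintf("cargo + TA duplication = %d bp (mod 3 = %d)", tot, tot %% 3L))
  report <- do.call(rbind, rules)
  attr(report, "valid") <- all(report$pass)
  report
}

#' Assemble the cargo sequence of a variant
#'
#' Concatenates `itr_up + spacer5 + reporter + spacer3 + itr_down` and
#' returns the sequence together with a segment map that tiles it exactly.
#'
#' @param variant A valid [transposon_variant()].
#' @return An object of class `cargo_sequence`: list with `residues`,
#'   `variant_name`, and `segment_map` (data.frame `segment`, `start`, `end`,
#'   1-based inclusive within the cargo; zero-length segments are kept with
#'   `end = start - 1`).
#' @export
build_cargo <- function(variant) {
  report <- validate_variant(variant)
  if (!attr(report, "valid")) {
    stop("invalid variant '", variant$name, "': ",
         paste(report$rule[!report$pass], collapse = ", "), call. = FALSE)
  }
  parts <- c(
    itr_up = variant$itr_up, spacer5 = variant$spacer5,
    reporter = variant$reporter, spacer3 = variant$spacer3,
    itr_down = variant$itr_down
  )
  len <- nchar(parts)
  end <- cumsum(len)
  start <- end - len + 1L
  structure(list(
    residues = paste(parts, collapse = ""),
    variant_name = variant$name,
    segment_map = data.frame(
      segment = names(parts), start = as.integer(start), end = as.integer(end),
      stringsAsFactors = FALSE
    )
  ), class = "cargo_sequence")
}

#' Scan an ITR for stop codons in the junction reading frame
#'
#' Translates the upstream junction context (the duplicated TA followed by the
#' ITR) in the frame implied by the codon phase of the target site, and
#' reports every stop codon encountered before the reporter. The frame per
#' phase:
#' * `P23`: the duplicated TA completes the interrupted codon, so the ITR is
#'   read from its first base in frame 0.
#' * `P31`: the duplicated A starts a fresh codon, so `A + ITR` is read.
#' * `P12`: the duplicated TA occupies codon positions 1-2, so `TA + ITR` is
#'   read; an ITR starting with A or G immediately forms a TAA/TAG stop at
#'   the junction.
#'
#' @param itr ITR sequence.
#' @param entry_phase `"P23"`, `"P31"` or `"P12"`.
#' @param preceded_by_ta Whether the junction TA context is prepended
#'   (default TRUE, the post-insertion situation).
#' @return A data.frame with columns `codon`, `aa_pos` (codon index within the
#'   scanned junction) and `nt_start` (1-based position of the codon start
#'   within the scanned junction string); zero rows when the frame is clean.
#' @export
scan_itr_stops <- function(itr, entry_phase, preceded_by_ta = TRUE) {
  stopifnot(entry_phase %in% PHASES)
  itr <- as_dna(itr, "ITR")
  prefix <- if (!preceded_by_ta) "" else {
    switch(entry_phase, P23 = "", P31 = "A", P12 = "TA")
  }
  junction <- paste0(prefix, itr)
  aa <- translate_dna(junction)
  hits <- which(strsplit(aa, "")[[1]] == "*")
  data.frame(
    codon = substr(rep(junction, length(hits)), (hits - 1L) * 3L + 1L,
                   hits * 3L),
    aa_pos = hits,
    nt_start = (hits - 1L) * 3L + 1L,
    stringsAsFactors = FALSE
  )
}

#' Enumerate ITR substitution variants
#'
#' Generates every combination of the allowed base substitutions at the given
#' ITR positions, and annotates each resulting ITR with its junction stop scan
#' for P12 entry (the phase whose junction frame reads straight through the
#' duplicated TA and therefore needs ITR modification).
#'
#' @param itr The ITR to mutate.
#' @param mutable_positions Integer vector of 1-based positions within the
#'   ITR.
#' @param allowed_substitutions List (same length) of character vectors of
#'   allowed bases per position.
#' @return A list of entries, each with `itr`, `substitutions` (named base
#'   vector), `p12_stops` (the [scan_itr_stops()] result) and `junction_clean`
#'   (TRUE iff no stop remains for P12 entry).
#' @export
generate_itr_variants <- function(itr, mutable_positions,
                                  allowed_substitutions) {
  itr <- as_dna(itr, "ITR")
  mutable_positions <- as.integer(mutable_positions)
  if (length(mutable_positions) != length(allowed_substitutions)) {
    stop("one substitution set required per mutable position", call. = FALSE)
  }
  if (any(mutable_positions < 1L | mutable_positions > nchar(itr))) {
    stop("mutable position outside ITR bounds", call. = FALSE)
  }
  if (any(vapply(allowed_substitutions, length, integer(1)) == 0L)) {
    stop("empty substitution set at a mutable position", call. = FALSE)
  }
  combos <- expand.grid(allowed_substitutions, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(combos)), function(i) {
    bases <- toupper(unlist(combos[i, ], use.names = FALSE))
    mutant <- itr
    for (j in seq_along(mutable_positions)) {
      substr(mutant, mutable_positions[j], mutable_positions[j]) <- bases[j]
    }
    stops <- scan_itr_stops(mutant, "P12")
    list(
      itr = mutant,
      substitutions = setNames(bases, mutable_positions),
      p12_stops = stops,
      junction_clean = nrow(stops) == 0L
    )
  })
}
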