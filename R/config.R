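# Structured (YAML) configuration: variant definitions and resolved run
# configs written alongside outputs for reproducibility.

#' Load transposon variant definitions from a YAML config file
#'
#' The file maps variant names to fields `reporter` (inline sequence) or
#' `reporter_fasta` (path, first record used), and optionally `itr_up`,
#' `itr_down`, `spacer5`, `spacer3`, `compatible_phase`, `reporter_name`.
#' Omitted fields fall back to the stock architecture for the variant name.
#'
#' @param path YAML file path.
#' @param base_dir Directory against which relative `reporter_fasta` paths are
#'   resolved (default: the config file's directory).
#' @return Named list of [transposon_variant()] objects.
#' @export
load_variant_config <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(names(cfg))) {
    stop("variant config must map variant names to definitions",
         call. = FALSE)
  }
  out <- lapply(names(cfg), function(nm) {
    def <- cfg[[nm]]
    reporter <- def$reporter
    if (is.null(reporter) && !is.null(def$reporter_fasta)) {
      fp <- def$reporter_fasta
      if (!file.exists(fp)) fp <- file.path(base_dir, fp)
      reporter <- unname(read_fasta(fp)[1L])
    }
    if (is.null(reporter)) {
      stop("variant ", nm, ": no reporter or reporter_fasta given",
           call. = FALSE)
    }
    transposon_variant(
      nm, reporter = reporter,
      reporter_name = def$reporter_name %||% "reporter",
      itr_up = def$itr_up %||% HIMAR_ITR,
      itr_down = def$itr_down %||% HIMAR_ITR,
      spacer5 = def$spacer5, spacer3 = def$spacer3,
      compatible_phase = def$compatible_phase
    )
  })
  names(out) <- names(cfg)
  out
}

#' Build the stock variant set with a given reporter
#'
#' Convenience wrapper producing the `open1`/`open2`/`open3` architectures
#' sharing one reporter and the default ITRs.
#'
#' @param reporter Reporter coding sequence.
#' @param reporter_name Reporter label.
#' @param include_open3 Include the open3 architecture (modelled and
#'   validated like the others; its junction-stop hazard with an unmodified
#'   ITR is reported by [scan_itr_stops()], not hidden).
#' @param ... Passed to [transposon_variant()].
#' @return Named list of [transposon_variant()] objects.
#' @export
stock_variants <- function(reporter, reporter_name = "reporter",
                           include_open3 = TRUE, ...) {
  nms <- c("open1", "open2", if (include_open3) "open3")
  setNames(lapply(nms, function(nm) {
    transposon_variant(nm, reporter = reporter,
                       reporter_name = reporter_name, ...)
  }), nms)
}

#' Write a resolved run configuration
#'
#' Serialises the exact parameter set of a run next to its outputs, together
#' with the package version and a content hash, so any output can be
#' regenerated.
#'
#' @param params Named list of resolved parameters.
#' @param path Output YAML path.
#' @return The config hash (md5 of the serialised YAML), invisibly.
#' @export
write_run_config <- function(params, path) {
  params$tool <- "tnfusion"
  params$version <- as.character(utils::packageVersion("tnfusion"))
  yaml::write_yaml(params, path)
  invisible(unname(tools::md5sum(path)))
}
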