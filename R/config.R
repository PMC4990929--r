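#' Default screening configuration
#'
#' Returns the nested list of tunable parameters shared by every stage of the
#' pipeline. All thresholds live here so that the synthetic-data generator and
#' the detectors always agree on one set of constants.
#'
#' @details Sections:
#' \describe{
#'   \item{efhand}{`templates` enabled loop templates; `threshold` minimum
#'     additive loop score for a hit (default 4.0); `max_hits` cap per protein
#'     (default 6).}
#'   \item{classify}{`nterm_window` residues inspected for N-terminal
#'     cysteines (default 30); `cterm_window` residues from the C-terminus in
#'     which an FPSF motif counts (default 40).}
#'   \item{naf}{`offset_min`/`offset_max` admissible 0-based offsets of the
#'     N-A-F tripeptide inside the 21-residue window (default 6--12);
#'     `threshold` minimum PSSM score in bits (default 0); `pseudocount` for
#'     PSSM construction (default 0.1).}
#'   \item{align}{`gap_open`, `gap_extend` affine gap costs (11, 1);
#'     `matrix` substitution matrix name (BLOSUM62); `poisson_correct`
#'     whether distances are -log(identity) instead of 1 - identity.}
#'   \item{prefilter}{`threshold_frac` fraction of the query self-score a
#'     local alignment must reach (default 0.25).}
#' }
#'
#' @param ... Named overrides, e.g. `screen_config(efhand = list(threshold = 5))`.
#'   Overrides are merged element-wise into the defaults.
#' @return Nested named list of class `screen_config`.
#' @export
#' @examples
#' cfg <- screen_config()
#' cfg$efhand$threshold
screen_config <- function(...) {
  cfg <- list(
    efhand = list(
      templates = c("L12", "L14", "L15", "L19"),
      threshold = 4.0,
      max_hits = 6L
    ),
    classify = list(
      nterm_window = 30L,
      cterm_window = 40L
    ),
    naf = list(
      offset_min = 6L,
      offset_max = 12L,
      threshold = 0,
      pseudocount = 0.1
    ),
    align = list(
      gap_open = 11,
      gap_extend = 1,
      matrix = "BLOSUM62",
      poisson_correct = FALSE
    ),
    prefilter = list(
      threshold_frac = 0.25
    ),
    seed = 1L
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(overrides[[nm]])) cfg[[nm]][[k]] <- overrides[[nm]][[k]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  structure(cfg, class = c("screen_config", "list"))
}

#' Read a configuration file
#'
#' Reads a YAML or JSON file whose structure mirrors [screen_config()] and
#' merges it over the defaults. Unknown keys are an error so typos in config
#' files do not pass silently.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `screen_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  parsed <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext, call. = FALSE)
  }
  defaults <- screen_config()
  unknown <- setdiff(names(parsed), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(screen_config, parsed)
}
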