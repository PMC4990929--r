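# FASTA, annotation and newick input/output.
#
# A protein set is a plain data.frame with columns id, species, sequence,
# description -- one row per protein. Sequences are upper-case strings over
# the 20 one-letter codes plus X; a single terminal '*' stop character is
# accepted on input and stripped.

#' Read a protein FASTA file
#'
#' Parses a FASTA file into a protein-set data.frame (columns `id`,
#' `species`, `sequence`, `description`). The id is the header token up to
#' the first whitespace; everything after it is the description. A species
#' tag is recovered from a `[species=...]` bracket in the description (the
#' convention [write_fasta()] uses), falling back to `species_hint`.
#'
#' @param path FASTA file path.
#' @param species_hint Species tag assigned to records whose headers carry no
#'   `[species=...]` tag. Default `"unknown"`.
#' @return data.frame with one row per entry, in input order. Sequences are
#'   upper-cased and a single terminal `*` is stripped.
#' @section Errors: an empty file, duplicate ids after normalization (the
#'   error names the id), and characters outside the amino-acid alphabet
#'   plus X (the error gives the position) are all rejected.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a first", "MGCF", ">b", "MK"), tf)
#' read_fasta(tf)
read_fasta <- function(path, species_hint = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("cannot parse FASTA file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0) stop("empty input: no FASTA records in ", path,
                             call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) stop("FASTA header with empty id in ", path,
                              call. = FALSE)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate-id error: id '", dup[1], "' occurs more than once",
         call. = FALSE)
  species <- vapply(desc, function(d) {
    m <- regmatches(d, regexec("\\[species=([^]]+)\\]", d))[[1]]
    if (length(m) == 2) m[2] else species_hint
  }, character(1), USE.NAMES = FALSE)

  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0)
      stop("record '", ids[i], "' has an empty sequence", call. = FALSE)
    bad <- regexpr(paste0("[^", paste(AA21, collapse = ""), "]"), seqs[i])
    if (bad > 0)
      stop(sprintf(
        "invalid-alphabet error in record '%s': character '%s' at position %d",
        ids[i], substr(seqs[i], bad, bad), bad), call. = FALSE)
  }
  data.frame(id = ids, species = species, sequence = unname(seqs),
             description = desc, stringsAsFactors = FALSE)
}

#' Write a protein set to FASTA
#'
#' Writes records with 60-column line wrapping. The species tag is embedded
#' in the header as `[species=...]` so that a write/read round trip
#' reproduces id, species and sequence exactly.
#'
#' @param records Protein-set data.frame (see [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("id", "species", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  header <- paste0(records$id, " [species=", records$species, "]",
                   ifelse(nzchar(desc), paste0(" ", desc), ""))
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- header
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Write per-protein annotations
#'
#' Serializes an annotation table to TSV (one row per protein, stable column
#' order) or JSON (lossless nesting of the same fields). All coordinates in
#' the output are 1-based inclusive.
#'
#' @param annotations data.frame of per-protein results; must contain at
#'   least `id` and `species`. The canonical leading column order is
#'   id, species, family, ef1_length, spacer12, naf_present, then motif
#'   flags and score fields; any further columns follow in given order.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param header Optional named character vector written as `# key=value`
#'   comment lines above a TSV (ignored for JSON, where it becomes a
#'   `meta` object).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path, format = c("tsv", "json"),
                              header = NULL) {
  format <- match.arg(format)
  stopifnot(is.data.frame(annotations))
  lead <- c("id", "species", "family", "ef1_length", "spacer12",
            "naf_present", "myristoylation", "cys3", "fpsf_position",
            "ef1_score", "naf_score")
  ord <- c(intersect(lead, names(annotations)),
           setdiff(names(annotations), lead))
  annotations <- annotations[, ord, drop = FALSE]
  if (format == "tsv") {
    con <- tryCatch(file(path, "w"),
                    error = function(e) stop("I/O error: cannot open ", path,
                                             call. = FALSE))
    on.exit(close(con))
    if (!is.null(header))
      writeLines(paste0("# ", names(header), "=", header), con)
    utils::write.table(annotations, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    payload <- list(meta = as.list(header %||% stats::setNames(list(), character(0))),
                    annotations = annotations)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read annotations written by [write_annotations()]
#'
#' @param path File path.
#' @param format `"tsv"` or `"json"`.
#' @return data.frame of annotations.
#' @export
read_annotations <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                      stringsAsFactors = FALSE)
  } else {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    as.data.frame(payload$annotations, stringsAsFactors = FALSE)
  }
}

#' Write a tree in newick format
#'
#' @param tree An `ape` `phylo` object with leaf labels and non-negative
#'   branch lengths.
#' @param path Output path.
#' @return `path`, invisibly. Duplicate leaf labels are an error.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels in tree", call. = FALSE)
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths in tree", call. = FALSE)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick tree
#'
#' @param path File path.
#' @return An `ape` `phylo` object.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
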