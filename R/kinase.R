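# CIPK candidate identification: a lightweight Ser/Thr kinase-core check
# plus detection of the 21-residue NAF regulatory domain. The NAF domain is
# named for its invariant Asn-Ala-Phe tripeptide, which is necessary and
# sufficient for CBL binding; a kinase with a catalytic core but no NAF
# domain is the decision boundary between CIPK and related SNF1-type
# kinases.

#' Detect a protein kinase catalytic core
#'
#' A deliberately crude proxy for Ser/Thr kinase family membership: the
#' sequence must contain the catalytic-loop anchor `HRD` followed by the
#' activation-segment anchor `DFG` with 10 to 60 residues between the end
#' of `HRD` and the start of `DFG`. It gates NAF calls; it is not a kinase
#' annotator.
#'
#' @param record Sequence string or one-row protein-set data.frame.
#' @return Logical.
#' @export
detect_kinase_core <- function(record) {
  sequence <- if (is.data.frame(record)) record$sequence[1] else record
  hrd <- gregexpr("HRD", sequence, fixed = TRUE)[[1]]
  if (hrd[1] == -1) return(FALSE)
  dfg <- gregexpr("DFG", sequence, fixed = TRUE)[[1]]
  if (dfg[1] == -1) return(FALSE)
  for (h in hrd) {
    gap <- dfg - (h + 3L)  # residues strictly between HRD and DFG
    if (any(gap >= 10L & gap <= 60L)) return(TRUE)
  }
  FALSE
}

#' Build a NAF-domain position-specific scoring matrix
#'
#' Log-odds PSSM over a uniform background from an ungapped alignment of
#' 21-residue NAF-domain sequences:
#' `entry(p, a) = log2((count(p, a) + pseudocount) / (n_rows + 20 * pseudocount)) - log2(1/20)`.
#'
#' @param seed_alignment Character vector of two or more 21-residue strings
#'   (no gaps). Rows may contain the ambiguity code X, which is ignored in
#'   the counts.
#' @param pseudocount Additive smoothing constant (default 0.1).
#' @return 21 x 20 numeric matrix (positions x residues) of class
#'   `naf_pssm`, in bits.
#' @export
build_naf_pssm <- function(seed_alignment, pseudocount = 0.1) {
  stopifnot(length(seed_alignment) >= 2, pseudocount >= 0)
  if (any(nchar(seed_alignment) != 21L))
    stop("all seed alignment rows must be exactly 21 residues", call. = FALSE)
  if (any(grepl("-", seed_alignment, fixed = TRUE)))
    stop("seed alignment rows must be ungapped", call. = FALSE)
  n <- length(seed_alignment)
  counts <- matrix(0L, nrow = 21, ncol = 20, dimnames = list(NULL, AA20))
  for (row in seed_alignment) {
    ch <- seq_chars(toupper(row))
    for (p in 1:21) {
      if (ch[p] %in% AA20) counts[p, ch[p]] <- counts[p, ch[p]] + 1L
    }
  }
  pssm <- log2((counts + pseudocount) / (n + 20 * pseudocount)) - log2(1 / 20)
  structure(pssm, class = c("naf_pssm", "matrix"),
            n_rows = n, pseudocount = pseudocount)
}

# Score a 21-residue window against a PSSM; X contributes 0.
score_naf_window <- function(window_chars, pssm) {
  s <- 0
  for (p in 1:21) {
    a <- window_chars[p]
    if (a %in% AA20) s <- s + pssm[p, a]
  }
  s
}

#' The packaged default NAF PSSM
#'
#' Builds the default PSSM from the seed alignment shipped with the package
#' (`inst/extdata/naf_seed_synthetic.txt`), which is generated from the
#' synthetic CIPK archetype family. Users screening real proteomes should
#' supply a curated seed alignment via [read_seed_alignment()].
#'
#' @param config A [screen_config()] list; uses `config$naf$pseudocount`.
#' @return A `naf_pssm` matrix.
#' @export
default_naf_pssm <- function(config = screen_config()) {
  path <- system.file("extdata", "naf_seed_synthetic.txt",
                      package = "cblscreen", mustWork = TRUE)
  build_naf_pssm(read_seed_alignment(path), config$naf$pseudocount)
}

#' Read a NAF seed alignment
#'
#' Accepts either plain text (one 21-residue sequence per line, `#` comments
#' allowed) or aligned FASTA.
#'
#' @param path File path.
#' @return Character vector of 21-residue strings.
#' @export
read_seed_alignment <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) > 0 && startsWith(lines[1], ">")) {
    recs <- read_fasta(path)
    return(recs$sequence)
  }
  toupper(lines)
}

#' Detect NAF-domain windows
#'
#' Every 21-residue window that contains a contiguous `NAF` tripeptide at an
#' admissible offset (default: 0-based offsets 6 to 12 within the window) is
#' scored against the PSSM. Windows at or above the score threshold become
#' hits; the tripeptide is a hard constraint, so no score can rescue a
#' window without it. Overlapping hits are resolved greedily by (score
#' descending, start ascending).
#'
#' @param record Sequence string or one-row protein-set data.frame.
#' @param pssm A `naf_pssm` matrix, e.g. [default_naf_pssm()].
#' @param config A [screen_config()] list; uses `config$naf`.
#' @return data.frame with 0-based half-open `start`, `end` (always
#'   `end - start == 21`), `naf_tripeptide_start` (0-based offset within the
#'   window), `pssm_score` (bits) and `invariants_satisfied` (always TRUE
#'   for emitted hits).
#' @export
detect_naf <- function(record, pssm = default_naf_pssm(),
                       config = screen_config()) {
  sequence <- if (is.data.frame(record)) record$sequence[1] else record
  stopifnot(inherits(pssm, "naf_pssm"))
  nafcfg <- config$naf
  n <- nchar(sequence)
  empty <- data.frame(start = integer(0), end = integer(0),
                      naf_tripeptide_start = integer(0),
                      pssm_score = numeric(0),
                      invariants_satisfied = logical(0))
  if (n < 21) return(empty)
  tri <- gregexpr("NAF", sequence, fixed = TRUE)[[1]]
  if (tri[1] == -1) return(empty)
  chars <- seq_chars(sequence)
  cand <- list()
  for (t1 in tri) {           # 1-based tripeptide start
    t0 <- t1 - 1L             # 0-based
    for (off in nafcfg$offset_min:nafcfg$offset_max) {
      s0 <- t0 - off
      if (s0 < 0 || s0 + 21L > n) next
      sc <- score_naf_window(chars[(s0 + 1L):(s0 + 21L)], pssm)
      if (sc >= nafcfg$threshold)
        cand[[length(cand) + 1L]] <-
          data.frame(start = s0, end = s0 + 21L, naf_tripeptide_start = off,
                     pssm_score = sc, invariants_satisfied = TRUE)
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$pssm_score, cand$start), , drop = FALSE]
  chosen <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(chosen) > 0 &&
        any(cand$start[i] < cand$end[chosen] &
            cand$start[chosen] < cand$end[i])) next
    chosen <- c(chosen, i)
  }
  cand <- cand[chosen, , drop = FALSE]
  cand <- cand[order(cand$start), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Call a protein as CIPK, NAF-less kinase, or non-kinase
#'
#' `CIPK` requires both a kinase core and at least one NAF-domain hit;
#' `KINASE_NO_NAF` is a kinase core without a NAF hit (the TvK650-type
#' architecture); everything else is `NOT_KINASE`.
#'
#' @inheritParams detect_naf
#' @return List of class `kinase_call`: `has_kinase_core`, `naf_hits`
#'   (data.frame), `verdict`.
#' @export
call_kinase <- function(record, pssm = default_naf_pssm(),
                        config = screen_config()) {
  core <- detect_kinase_core(record)
  hits <- detect_naf(record, pssm, config)
  verdict <- if (core && nrow(hits) >= 1) "CIPK"
  else if (core) "KINASE_NO_NAF"
  else "NOT_KINASE"
  structure(list(has_kinase_core = core, naf_hits = hits, verdict = verdict),
            class = "kinase_call")
}

#' @export
print.kinase_call <- function(x, ...) {
  cat("Kinase call:", x$verdict,
      sprintf("(core=%s, NAF hits=%d)\n", x$has_kinase_core, nrow(x$naf_hits)))
  invisible(x)
}
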