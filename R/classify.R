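# Sensor family classification.
#
# Families: CAM_LIKE (calmodulin: canonical 12-residue EF1, D at X, L after
# -Z), CNB_NCS_LIKE (calcineurin B / neuronal calcium sensors: canonical
# EF1, D at X, F after -Z), CBL_PLANT (14-residue EF1 with S at X, the
# invariant 23-residue EF1-EF2 spacer and an N-terminal membrane-targeting
# motif), CBL_NONPLANT (14-residue EF1 with S at X, variable spacer),
# CBL_STRAMENOPILE (15-residue EF1, S-to-L exchange at X, inserted G and/or
# Q-[HN]-E motif), CBL_EXTENDED (19-residue EF1), CBL_DEGENERATE (S-to-A
# exchange at X with the single-residue insertion seen in divergent
# parabasalid CBLs), UNCLASSIFIED.

SENSOR_FAMILIES <- c("CAM_LIKE", "CNB_NCS_LIKE", "CBL_PLANT", "CBL_NONPLANT",
                     "CBL_STRAMENOPILE", "CBL_EXTENDED", "CBL_DEGENERATE",
                     "UNCLASSIFIED")

#' Detect N-terminal lipid-modification motifs
#'
#' Flags the N-myristoylation consensus M-G-x-x-x-[ST] anchored at residue 1
#' (the modification site is the glycine at position 2), a cysteine at
#' position 3 (the conserved palmitoylation/S-acylation site of plasma
#' membrane targeted plant CBLs), and counts cysteines in the N-terminal
#' window (multiple S-acylation sites redirect targeting to the tonoplast).
#'
#' @param record Sequence string or one-row protein-set data.frame.
#' @param nterm_window Residues counted for `n_cys_nterm` (default 30,
#'   minimum 6).
#' @return List with logical `myristoylation`, logical `cys3`, integer
#'   `n_cys_nterm`.
#' @export
#' @examples
#' detect_lipid_motifs("MGCAASKKLI")
detect_lipid_motifs <- function(record, nterm_window = 30L) {
  sequence <- if (is.data.frame(record)) record$sequence[1] else record
  stopifnot(nterm_window >= 6)
  n <- nchar(sequence)
  ch <- seq_chars(sequence)
  myr <- n >= 6 && ch[1] == "M" && ch[2] == "G" && ch[6] %in% c("S", "T")
  cys3 <- n >= 3 && ch[3] == "C"
  n_cys <- sum(ch[seq_len(min(n, nterm_window))] == "C")
  list(myristoylation = myr, cys3 = cys3, n_cys_nterm = as.integer(n_cys))
}

#' Detect the C-terminal FPSF phosphorylation motif
#'
#' Plant CBLs are phosphorylated by their partner CIPK within a conserved
#' FPSF tetrapeptide close to the C-terminus. Reports the 1-based start of
#' the last FPSF occurrence that begins within the final `cterm_window`
#' residues, or `NA` when there is none.
#'
#' @param record Sequence string or one-row protein-set data.frame.
#' @param cterm_window Search window from the C-terminus (default 40,
#'   minimum 4).
#' @return Integer position or `NA_integer_`.
#' @export
detect_fpsf <- function(record, cterm_window = 40L) {
  sequence <- if (is.data.frame(record)) record$sequence[1] else record
  stopifnot(cterm_window >= 4)
  n <- nchar(sequence)
  m <- gregexpr("FPSF", sequence, fixed = TRUE)[[1]]
  if (m[1] == -1) return(NA_integer_)
  inwin <- m[m >= max(1L, n - cterm_window + 1L)]
  if (length(inwin) == 0) return(NA_integer_)
  as.integer(max(inwin))
}

#' Classify an EF-hand protein into a calcium-sensor family
#'
#' Applies the ordered structural rules to the first four EF-hand hits
#' (later hits are ignored for the verdict but counted):
#' \enumerate{
#'   \item fewer than two EF-hands: UNCLASSIFIED;
#'   \item canonical 12-residue EF1 with D at X: CAM_LIKE when an L follows
#'     the -Z position, CNB_NCS_LIKE when an F does (low-confidence
#'     CNB_NCS_LIKE otherwise);
#'   \item 14-residue EF1 with S at X: CBL_PLANT when the EF1-EF2 spacer is
#'     exactly 23 residues and an N-terminal targeting motif
#'     (myristoylation or the position-3 cysteine) is present, CBL_NONPLANT
#'     otherwise;
#'   \item 15-residue EF1 with L at X and the inserted G or Q-[HN]-E motif:
#'     CBL_STRAMENOPILE;
#'   \item 19-residue EF1: CBL_EXTENDED;
#'   \item 14- or 15-residue EF1 with A at X: CBL_DEGENERATE;
#'   \item otherwise, F after -Z with at least four EF-hands gives a
#'     low-confidence CBL_NONPLANT, else UNCLASSIFIED.
#' }
#' Every rule consulted is recorded in the evidence list.
#'
#' @param record Sequence string or one-row protein-set data.frame.
#' @param hits EF-hand hits from [scan_ef_hands()] on the same sequence.
#' @param config A [screen_config()] list; uses `config$classify`.
#' @return List of class `sensor_classification`: `family`, `n_ef_hands`,
#'   `ef1_template`, `x_residue`, `post_minus_z`, `spacer12`, `lipid` (see
#'   [detect_lipid_motifs()]), `fpsf_position`, `evidence` (character
#'   vector).
#' @export
classify_sensor <- function(record, hits, config = screen_config()) {
  sequence <- if (is.data.frame(record)) record$sequence[1] else record
  check_hits(hits)
  lipid <- detect_lipid_motifs(sequence, config$classify$nterm_window)
  fpsf <- detect_fpsf(sequence, config$classify$cterm_window)
  n_hits <- nrow(hits)
  used <- hits[seq_len(min(4L, n_hits)), , drop = FALSE]
  spacers <- if (nrow(used) >= 2) compute_spacers(used) else integer(0)
  spacer12 <- if (length(spacers) >= 1) spacers[1] else NA_integer_

  ef1_template <- if (n_hits >= 1) used$template[1] else NA_character_
  x_res <- if (n_hits >= 1) used$x_res[1] else NA_character_
  post <- if (n_hits >= 1) used$post_minus_z_res[1] else NA_character_

  evidence <- character(0)
  note <- function(msg) evidence <<- c(evidence, msg)
  family <- NULL

  note(sprintf("rule1: n_ef_hands=%d", n_hits))
  if (n_hits < 2) {
    family <- "UNCLASSIFIED"
  }
  if (is.null(family)) {
    note(sprintf("rule2: ef1=%s x=%s post_minus_z=%s", ef1_template, x_res, post))
    if (ef1_template == "L12" && x_res == "D") {
      if (post == "L") {
        family <- "CAM_LIKE"
        note("rule2: canonical EF1, D at X, L after -Z -> CAM_LIKE")
      } else if (post == "F") {
        family <- "CNB_NCS_LIKE"
        note("rule2: canonical EF1, D at X, F after -Z -> CNB_NCS_LIKE")
      } else {
        family <- "CNB_NCS_LIKE"
        note("rule2: canonical EF1, D at X, atypical post--Z residue -> CNB_NCS_LIKE (low confidence)")
      }
    }
  }
  if (is.null(family)) {
    note(sprintf("rule3: spacer12=%s myristoylation=%s cys3=%s",
                 spacer12, lipid$myristoylation, lipid$cys3))
    if (ef1_template == "L14" && x_res == "S") {
      if (!is.na(spacer12) && spacer12 == 23L &&
          (lipid$myristoylation || lipid$cys3)) {
        family <- "CBL_PLANT"
        note("rule3: 14-residue EF1, S at X, invariant 23-residue spacer and targeting motif -> CBL_PLANT")
      } else {
        family <- "CBL_NONPLANT"
        note("rule3: 14-residue EF1, S at X -> CBL_NONPLANT")
      }
    }
  }
  if (is.null(family)) {
    if (ef1_template == "L15" && x_res == "L" &&
        (isTRUE(used$qhe_motif[1]) || isTRUE(used$insert_has_g[1]))) {
      family <- "CBL_STRAMENOPILE"
      note("rule4: 15-residue EF1, S-to-L exchange at X with inserted G / Q-[HN]-E -> CBL_STRAMENOPILE")
    } else {
      note("rule4: not a stramenopile-type EF1")
    }
  }
  if (is.null(family)) {
    if (ef1_template == "L19") {
      family <- "CBL_EXTENDED"
      note("rule5: 19-residue EF1 -> CBL_EXTENDED")
    } else {
      note("rule5: EF1 is not a 19-residue loop")
    }
  }
  if (is.null(family)) {
    if (ef1_template %in% c("L14", "L15") && x_res == "A") {
      family <- "CBL_DEGENERATE"
      note("rule6: extended EF1 with S-to-A exchange at X -> CBL_DEGENERATE")
    } else {
      note("rule6: no S-to-A exchange at X")
    }
  }
  if (is.null(family)) {
    if (post == "F" && n_hits >= 4) {
      family <- "CBL_NONPLANT"
      note("rule7: F after -Z with four EF-hands -> CBL_NONPLANT (low confidence)")
    } else {
      family <- "UNCLASSIFIED"
      note("rule7: no rule matched -> UNCLASSIFIED")
    }
  }

  structure(list(
    family = family,
    n_ef_hands = as.integer(n_hits),
    ef1_template = ef1_template,
    x_residue = x_res,
    post_minus_z = post,
    spacer12 = spacer12,
    lipid = lipid,
    fpsf_position = fpsf,
    evidence = evidence
  ), class = "sensor_classification")
}

#' @export
print.sensor_classification <- function(x, ...) {
  cat("Sensor classification:", x$family, "\n")
  cat(sprintf("  EF-hands: %d (EF1 %s, X=%s, post--Z=%s, spacer12=%s)\n",
              x$n_ef_hands, x$ef1_template, x$x_residue, x$post_minus_z,
              ifelse(is.na(x$spacer12), "NA", x$spacer12)))
  cat(sprintf("  lipid: myristoylation=%s cys3=%s n_cys=%d; FPSF at %s\n",
              x$lipid$myristoylation, x$lipid$cys3, x$lipid$n_cys_nterm,
              ifelse(is.na(x$fpsf_position), "none", x$fpsf_position)))
  invisible(x)
}
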