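# EF-hand loop detection.
#
# An EF-hand coordinates Ca2+ with six loop residues, labeled X, Y, Z, -Y,
# -X, -Z. The canonical loop spans 12 residues (coordinating offsets
# 0,2,4,6,8,11). CBL-type sensors carry extended first EF-hands in which
# extra residues are inserted between the X and Y coordinates: a 14-residue
# loop (plant/non-plant CBLs), a 15-residue loop (stramenopile CBLs, with a
# G in the insertion and a Q-[HN]-E motif), and a 19-residue loop
# (Aphanomyces/Saprolegnia-type). The -Z coordinate always sits at the last
# loop position; all extension is between X and Y.

LOOP_TEMPLATES <- local({
  mk <- function(name, len, ins) {
    list(name = name, loop_length = len, insert_length = ins,
         offsets = c(X = 0L, Y = 2L + ins, Z = 4L + ins, mY = 6L + ins,
                     mX = 8L + ins, mZ = len - 1L))
  }
  list(L12 = mk("L12", 12L, 0L), L14 = mk("L14", 14L, 2L),
       L15 = mk("L15", 15L, 3L), L19 = mk("L19", 19L, 7L))
})

#' Loop template lookup
#'
#' @param name One of `"L12"`, `"L14"`, `"L15"`, `"L19"`.
#' @return List with `name`, `loop_length`, `insert_length` (residues
#'   inserted between the X and Y coordinates) and the six 0-based
#'   `offsets` of X, Y, Z, -Y, -X, -Z within the loop.
#' @export
loop_template <- function(name) {
  tpl <- LOOP_TEMPLATES[[name]]
  if (is.null(tpl)) stop("unknown loop template: ", name, call. = FALSE)
  tpl
}

# Per-template residue weight lookups over AA21 (X scores 0 everywhere).
loop_weights <- function(template) {
  w0 <- function() stats::setNames(numeric(21), AA21)
  anchor <- w0() - 5; anchor[c("E", "D", "X")] <- c(3, 1.5, 0)
  xw <- w0() - 2; xw[c("D", "S", "N", "X")] <- c(2, 2, 1, 0)
  if (template$name == "L15") xw[c("A", "L")] <- c(1, 1.5)
  yz <- w0(); yz[c("D", "N", "S", "T", "E", "G", "Q")] <- 1
  mx <- w0(); mx[c("D", "N", "S", "T", "E", "G")] <- 0.5
  list(anchor = anchor, x = xw, yz = yz, mx = mx)
}

# Q-[HN]-E search region for the 15-residue loop: the triplet must lie
# within loop offsets 4..10 (middle part of the loop), so the Q may start at
# offsets 4..8.
QHE_START_OFFSETS <- 4:8

l15_bonuses <- function(si, starts, template) {
  # starts: 1-based window start indices into encoded sequence si
  g_idx <- match("G", AA21)
  q_idx <- match("Q", AA21); h_idx <- match("H", AA21)
  n_idx <- match("N", AA21); e_idx <- match("E", AA21)
  ins_off <- seq_len(template$offsets[["Y"]] - 1L)  # offsets 1..Y-1
  has_g <- rep(FALSE, length(starts))
  for (o in ins_off) has_g <- has_g | (si[starts + o] == g_idx)
  qhe <- rep(FALSE, length(starts))
  for (q in QHE_START_OFFSETS) {
    qhe <- qhe | (si[starts + q] == q_idx &
                  si[starts + q + 1L] %in% c(h_idx, n_idx) &
                  si[starts + q + 2L] == e_idx)
  }
  list(insert_has_g = has_g, qhe_motif = qhe)
}

# Vectorized window scores for one template over all valid starts.
scan_template <- function(si, template) {
  n <- length(si)
  len <- template$loop_length
  if (n < len)
    return(list(starts = integer(0), score = numeric(0),
                insert_has_g = logical(0), qhe_motif = logical(0)))
  starts <- seq_len(n - len + 1L)  # 1-based
  w <- loop_weights(template)
  off <- template$offsets
  score <- w$anchor[si[starts + off[["mZ"]]]] +
    w$x[si[starts + off[["X"]]]] +
    w$yz[si[starts + off[["Y"]]]] +
    w$yz[si[starts + off[["Z"]]]] +
    w$mx[si[starts + off[["mX"]]]]
  if (template$name == "L15") {
    b <- l15_bonuses(si, starts, template)
    score <- score + b$insert_has_g + b$qhe_motif
  } else {
    b <- list(insert_has_g = rep(FALSE, length(starts)),
              qhe_motif = rep(FALSE, length(starts)))
  }
  list(starts = starts, score = unname(score),
       insert_has_g = b$insert_has_g, qhe_motif = b$qhe_motif)
}

#' Score one candidate EF-hand loop window
#'
#' Deterministic additive score of a window against a loop template: the -Z
#' anchor contributes +3 for E, +1.5 for D and -5 otherwise; the X
#' coordinate +2 for D or S, +1 for N (for the 15-residue template also +1
#' for A and +1.5 for L), -2 otherwise; Y and Z +1 each when drawn from
#' \{D,N,S,T,E,G,Q\}; -X +0.5 when from \{D,N,S,T,E,G\}; -Y coordinates via
#' the backbone and accepts any residue. The 15-residue template earns +1
#' for a G inside the X--Y insertion and +1 for a Q-[HN]-E triplet in the
#' middle of the loop (offsets 4--10). The ambiguity code X contributes 0 at
#' every position.
#'
#' @param window Residue string whose length equals the template loop length.
#' @param template Template name or a [loop_template()] list.
#' @param config A [screen_config()] list (reserved for weight overrides).
#' @return Numeric score (unitless).
#' @export
#' @examples
#' score_loop("DKDGDGTITTKE", "L12")
score_loop <- function(window, template, config = screen_config()) {
  if (is.character(template)) template <- loop_template(template)
  if (nchar(window) != template$loop_length)
    stop(sprintf("window length %d does not match template %s (%d)",
                 nchar(window), template$name, template$loop_length),
         call. = FALSE)
  si <- encode_seq(window)
  scan_template(si, template)$score[1]
}

empty_hits <- function() {
  data.frame(loop_start = integer(0), loop_end = integer(0),
             template = character(0), x_res = character(0),
             y_res = character(0), z_res = character(0),
             minus_y_res = character(0), minus_x_res = character(0),
             minus_z_res = character(0), post_minus_z_res = character(0),
             qhe_motif = logical(0), insert_has_g = logical(0),
             score = numeric(0), stringsAsFactors = FALSE)
}

#' Scan a protein for EF-hand loops
#'
#' Scores every window of every enabled loop template and reports the
#' windows at or above the score threshold, resolved to a non-overlapping
#' set greedily by (score descending, start ascending, longer template
#' first), capped at `max_hits` hits. Hits are returned sorted by start and
#' carry the six coordinating residues plus the residue immediately
#' following the loop (`post_minus_z_res`; `"-"` when the loop ends the
#' sequence).
#'
#' @param record A sequence string, or a one-row protein-set data.frame.
#' @param config A [screen_config()] list; uses `config$efhand`.
#' @return data.frame of hits with 0-based half-open `loop_start`,
#'   `loop_end` coordinates. Zero rows when nothing is found.
#' @export
#' @examples
#' hits <- scan_ef_hands(paste0("MAAAA", "DKDGDGTITTKE", "FAAAA"))
#' hits$template
scan_ef_hands <- function(record, config = screen_config()) {
  sequence <- if (is.data.frame(record)) record$sequence[1] else record
  stopifnot(is.character(sequence), length(sequence) == 1)
  ef <- config$efhand
  si <- encode_seq(sequence)

  cand <- list()
  for (tname in ef$templates) {
    tpl <- loop_template(tname)
    sc <- scan_template(si, tpl)
    keep <- which(sc$score >= ef$threshold)
    if (length(keep) == 0) next
    cand[[tname]] <- data.frame(
      start0 = sc$starts[keep] - 1L, template = tname,
      loop_length = tpl$loop_length, score = sc$score[keep],
      insert_has_g = sc$insert_has_g[keep], qhe_motif = sc$qhe_motif[keep],
      stringsAsFactors = FALSE)
  }
  if (length(cand) == 0) return(empty_hits())
  cand <- do.call(rbind, cand)

  # Greedy overlap resolution: best score first, then leftmost, then the
  # longer template, then template name for full determinism.
  ord <- order(-cand$score, cand$start0, -cand$loop_length, cand$template)
  cand <- cand[ord, , drop = FALSE]
  chosen <- integer(0)
  ends <- integer(0)
  for (i in seq_len(nrow(cand))) {
    s <- cand$start0[i]; e <- s + cand$loop_length[i]
    if (length(chosen) > 0 &&
        any(s < cand$start0[chosen] + cand$loop_length[chosen] &
            cand$start0[chosen] < e)) next
    chosen <- c(chosen, i)
    if (length(chosen) >= ef$max_hits) break
  }
  cand <- cand[chosen, , drop = FALSE]
  cand <- cand[order(cand$start0), , drop = FALSE]

  chars <- seq_chars(sequence)
  res_at <- function(start0, off) chars[start0 + off + 1L]
  tpls <- lapply(cand$template, loop_template)
  offmat <- vapply(tpls, function(t) t$offsets, integer(6))
  hit <- data.frame(
    loop_start = cand$start0,
    loop_end = cand$start0 + cand$loop_length,
    template = cand$template,
    x_res = res_at(cand$start0, offmat["X", ]),
    y_res = res_at(cand$start0, offmat["Y", ]),
    z_res = res_at(cand$start0, offmat["Z", ]),
    minus_y_res = res_at(cand$start0, offmat["mY", ]),
    minus_x_res = res_at(cand$start0, offmat["mX", ]),
    minus_z_res = res_at(cand$start0, offmat["mZ", ]),
    post_minus_z_res = ifelse(cand$start0 + cand$loop_length < length(chars),
                              chars[pmin(cand$start0 + cand$loop_length + 1L,
                                         length(chars))], "-"),
    qhe_motif = cand$qhe_motif,
    insert_has_g = cand$insert_has_g,
    score = cand$score,
    stringsAsFactors = FALSE)
  rownames(hit) <- NULL
  hit
}

#' Spacer lengths between consecutive EF-hand hits
#'
#' The spacer is the count of residues strictly between consecutive loops:
#' `loop_start[i+1] - loop_end[i]`. In land-plant CBLs the first spacer
#' (EF1 to EF2) is invariant at 23 residues; in non-plant species it varies
#' from 19 to 24.
#'
#' @param hits Hit data.frame from [scan_ef_hands()], sorted and
#'   non-overlapping.
#' @return Integer vector of length `nrow(hits) - 1` (empty for fewer than
#'   two hits).
#' @export
compute_spacers <- function(hits) {
  check_hits(hits)
  if (nrow(hits) < 2) return(integer(0))
  as.integer(hits$loop_start[-1] - hits$loop_end[-nrow(hits)])
}

# Contract check shared by compute_spacers and classify_sensor.
check_hits <- function(hits) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) < 2) return(invisible(TRUE))
  if (is.unsorted(hits$loop_start, strictly = TRUE))
    stop("hits must be sorted by loop_start", call. = FALSE)
  if (any(hits$loop_start[-1] < hits$loop_end[-nrow(hits)]))
    stop("hits must be non-overlapping", call. = FALSE)
  invisible(TRUE)
}
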