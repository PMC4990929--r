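# Synthetic archetype and proteome generator.
#
# Each archetype family instantiates one of the protein architectures the
# screen is built to recognize. Sensor archetypes share a common scaffold --
# fixed consensus residues for the four calcium-binding loops and the
# inter-loop spacers, emulating the global homology of a real sensor family
# -- and differ in the family-defining features: the first-EF-hand template,
# the X-coordinate residue, the residue after the -Z position, the EF1-EF2
# spacer length, the N-terminal lipid-modification motif and the C-terminal
# FPSF motif. N- and C-terminal tails are drawn from a uniform background by
# seeded RNG; tail draws that would plant an unintended above-threshold
# EF-hand window (or a spurious sequence motif) are resampled, so the
# emitted ground truth is exact by construction. Substitution noise is then
# applied on top, sparing only the constrained positions: the six
# coordinating residues of every loop, the post--Z residue, motif anchors
# and the NAF tripeptide.

ARCHETYPE_FAMILIES <- c(SENSOR_FAMILIES[SENSOR_FAMILIES != "UNCLASSIFIED"],
                        "CIPK", "KINASE_NO_NAF", "DECOY")

# Loop consensus strings. Coordinating offsets score the maximum the loop
# template allows; filler residues are part of the shared scaffold.
SCAFFOLD <- list(
  loop12 = "DKDGDGTITTKE",
  ef1 = c(CAM_LIKE = "DKDGDGTITTKE",
          CNB_NCS_LIKE = "DKDGDGTITTKE",
          CBL_PLANT = "SAAKDGDGTITTKE",
          CBL_NONPLANT = "SAAKDGDGTITTKE",
          CBL_STRAMENOPILE = "LAGAKDGDQHETIKE",
          CBL_EXTENDED = "SAGAAKAGADGDGTITTKE",
          CBL_DEGENERATE = "AASAKDGDGITTIKE"),
  ef1_template = c(CAM_LIKE = "L12", CNB_NCS_LIKE = "L12",
                   CBL_PLANT = "L14", CBL_NONPLANT = "L14",
                   CBL_STRAMENOPILE = "L15", CBL_EXTENDED = "L19",
                   CBL_DEGENERATE = "L15"),
  post = c(CAM_LIKE = "L", CNB_NCS_LIKE = "F", CBL_PLANT = "F",
           CBL_NONPLANT = "F", CBL_STRAMENOPILE = "F", CBL_EXTENDED = "F",
           CBL_DEGENERATE = "F"),
  # Spacer filler drawn from residues that can neither serve as an EF-hand
  # -Z anchor nor as a favorable X coordinate, so the fixed scaffold itself
  # can never spawn a competing loop window.
  spacer_fill = "KGKFQIGKTVQGMRGWVKPTQIK",
  naf = "ELSRLSVNAFDLISLSEGRNK",   # invariant N-A-F at window offset 7
  naf_tripeptide_offset = 7L
)

NTERM_LEN <- 30L
CTERM_PLANT <- 40L
CTERM_OTHER <- 25L

draw_bg <- function(n) sample(AA20, n, replace = TRUE)

# Assemble the zero-noise layout for one archetype. Returns chars, masks and
# ground truth. `random` marks positions drawn by seeded RNG (resampleable);
# `protected` marks positions the noise process must never touch.
sensor_layout <- function(family, spacer12) {
  ef1 <- SCAFFOLD$ef1[[family]]
  tpl1 <- SCAFFOLD$ef1_template[[family]]
  post <- SCAFFOLD$post[[family]]
  l12 <- SCAFFOLD$loop12
  fill <- function(len) seq_chars(SCAFFOLD$spacer_fill)[seq_len(len)]

  chars <- character(0); random <- logical(0); protected <- logical(0)
  add <- function(piece, rnd, prot) {
    chars <<- c(chars, piece)
    random <<- c(random, rep_len(rnd, length(piece)))
    protected <<- c(protected, rep_len(prot, length(piece)))
  }

  # N-terminus
  if (family == "CBL_PLANT") {
    nt <- c("M", "G", "C", draw_bg(2), "S", draw_bg(NTERM_LEN - 6L))
    add(nt, rnd = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE,
                    rep(TRUE, NTERM_LEN - 6L)),
        prot = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE,
                 rep(FALSE, NTERM_LEN - 6L)))
  } else {
    add(c("M", draw_bg(NTERM_LEN - 1L)),
        rnd = c(FALSE, rep(TRUE, NTERM_LEN - 1L)), prot = FALSE)
  }

  loops <- data.frame(start = integer(0), end = integer(0),
                      template = character(0), stringsAsFactors = FALSE)
  add_loop <- function(loop_str, tname) {
    tpl <- loop_template(tname)
    prot <- rep(FALSE, tpl$loop_length)
    prot[tpl$offsets + 1L] <- TRUE
    loops <<- rbind(loops, data.frame(
      start = length(chars), end = length(chars) + tpl$loop_length,
      template = tname, stringsAsFactors = FALSE))
    add(seq_chars(loop_str), rnd = FALSE, prot = prot)
  }
  add_spacer <- function(len) {
    # post--Z residue first, then scaffold filler
    add(post, rnd = FALSE, prot = TRUE)
    add(fill(len - 1L), rnd = FALSE, prot = FALSE)
  }

  add_loop(ef1, tpl1)
  add_spacer(spacer12)
  add_loop(l12, "L12"); add_spacer(23L)
  add_loop(l12, "L12"); add_spacer(23L)
  add_loop(l12, "L12")

  # C-terminus (starts with the post--Z residue of EF4)
  fpsf_position <- NA_integer_
  if (family == "CBL_PLANT") {
    add(post, rnd = FALSE, prot = TRUE)
    add(draw_bg(CTERM_PLANT - 15L), rnd = TRUE, prot = FALSE)
    fpsf_position <- length(chars) + 1L
    add(c("F", "P", "S", "F"), rnd = FALSE, prot = TRUE)
    add(draw_bg(10L), rnd = TRUE, prot = FALSE)
  } else {
    add(post, rnd = FALSE, prot = TRUE)
    add(draw_bg(CTERM_OTHER - 1L), rnd = TRUE, prot = FALSE)
  }

  list(chars = chars, random = random, protected = protected,
       truth = list(family = family, ef1_template = tpl1, loops = loops,
                    spacers = c(spacer12, 23L, 23L),
                    myristoylation = family == "CBL_PLANT",
                    cys3 = family == "CBL_PLANT",
                    fpsf_position = fpsf_position,
                    naf = NULL, kinase_core = NULL))
}

kinase_layout <- function(family) {
  chars <- character(0); random <- logical(0); protected <- logical(0)
  add <- function(piece, rnd, prot) {
    chars <<- c(chars, piece)
    random <<- c(random, rep_len(rnd, length(piece)))
    protected <<- c(protected, rep_len(prot, length(piece)))
  }
  add(c("M", draw_bg(14L)), rnd = c(FALSE, rep(TRUE, 14L)), prot = FALSE)
  hrd_start <- length(chars)                 # 0-based
  add(c("H", "R", "D"), rnd = FALSE, prot = TRUE)
  add(draw_bg(30L), rnd = TRUE, prot = FALSE)
  dfg_start <- length(chars)
  add(c("D", "F", "G"), rnd = FALSE, prot = TRUE)
  add(draw_bg(40L), rnd = TRUE, prot = FALSE)
  naf <- NULL
  if (family == "CIPK") {
    naf_start <- length(chars)
    naf_chars <- seq_chars(SCAFFOLD$naf)
    toff <- SCAFFOLD$naf_tripeptide_offset
    prot <- rep(FALSE, 21L); prot[toff + 1:3] <- TRUE
    add(naf_chars, rnd = FALSE, prot = prot)
    naf <- list(start = naf_start, end = naf_start + 21L,
                tripeptide_offset = toff)
    add(draw_bg(20L), rnd = TRUE, prot = FALSE)
  } else {
    add(draw_bg(81L), rnd = TRUE, prot = FALSE)
  }
  list(chars = chars, random = random, protected = protected,
       truth = list(family = family, ef1_template = NA_character_,
                    loops = NULL, spacers = integer(0),
                    myristoylation = FALSE, cys3 = FALSE,
                    fpsf_position = NA_integer_, naf = naf,
                    kinase_core = list(hrd_start = hrd_start,
                                       dfg_start = dfg_start)))
}

# Positions (1-based) implicated in any deviation of the assembled sequence
# from its planted ground truth: spurious or displaced EF-hand hits, motif
# flags that contradict the architecture, an accidental kinase core in a
# sensor, or a stray NAF tripeptide in a kinase.
layout_violations <- function(lay, config) {
  seqstr <- paste(lay$chars, collapse = "")
  bad <- integer(0)
  if (!is.null(lay$truth$loops)) {
    hits <- scan_ef_hands(seqstr, config)
    planted <- lay$truth$loops
    hk <- paste(hits$loop_start, hits$template)
    pk <- paste(planted$start, planted$template)
    spurious <- hits[!(hk %in% pk), , drop = FALSE]
    if (nrow(spurious) > 0)
      bad <- c(bad, unlist(lapply(seq_len(nrow(spurious)), function(i)
        (spurious$loop_start[i] + 1L):spurious$loop_end[i])))
    lm <- detect_lipid_motifs(seqstr, config$classify$nterm_window)
    if (lm$myristoylation != lay$truth$myristoylation) bad <- c(bad, 2L, 6L)
    if (lm$cys3 != lay$truth$cys3) bad <- c(bad, 3L)
    fp <- detect_fpsf(seqstr, config$classify$cterm_window)
    want_fp <- lay$truth$fpsf_position
    if (!identical(fp, want_fp) && !(is.na(fp) && is.na(want_fp))) {
      occ <- gregexpr("FPSF", seqstr, fixed = TRUE)[[1]]
      occ <- occ[is.na(want_fp) | occ != want_fp]
      bad <- c(bad, unlist(lapply(occ, function(p) p:(p + 3L))))
    }
    if (detect_kinase_core(seqstr)) {
      occ <- c(gregexpr("HRD", seqstr, fixed = TRUE)[[1]],
               gregexpr("DFG", seqstr, fixed = TRUE)[[1]])
      bad <- c(bad, unlist(lapply(occ[occ > 0], function(p) p:(p + 2L))))
    }
  } else if (lay$truth$family != "DECOY") {
    occ <- gregexpr("NAF", seqstr, fixed = TRUE)[[1]]
    occ <- occ[occ > 0]
    planted_tri <- if (!is.null(lay$truth$naf))
      lay$truth$naf$start + lay$truth$naf$tripeptide_offset + 1L else -1L
    occ <- occ[occ != planted_tri]
    if (length(occ) > 0)
      bad <- c(bad, unlist(lapply(occ, function(p) p:(p + 2L))))
  }
  unique(bad)
}

# Resample seeded-random positions until the assembled sequence carries
# exactly the planted signals and nothing else.
clean_layout <- function(lay, family, config) {
  for (iter in 1:200) {
    bad <- layout_violations(lay, config)
    bad <- bad[lay$random[bad]]
    if (length(bad) == 0) {
      if (length(layout_violations(lay, config)) > 0)
        stop("internal scaffold error: unresolvable spurious hit",
             call. = FALSE)
      return(lay)
    }
    lay$chars[bad] <- draw_bg(length(bad))
  }
  stop("archetype cleaning did not converge", call. = FALSE)
}

# Within-species paralog divergence: substitute unconstrained positions at
# `rate`, then revert any substitution that would corrupt the planted
# ground truth. Models recent gene duplication, where paralogs are near
# copies; reverting keeps coordinates and labels exact.
diverge_layout <- function(lay, rate, config) {
  if (rate <= 0) return(lay)
  base <- lay$chars
  lay <- apply_noise(lay, rate)
  for (iter in 1:50) {
    bad <- layout_violations(lay, config)
    bad <- bad[lay$chars[bad] != base[bad]]
    if (length(bad) == 0) {
      if (length(layout_violations(lay, config)) > 0)
        stop("internal scaffold error after divergence", call. = FALSE)
      return(lay)
    }
    lay$chars[bad] <- base[bad]
  }
  stop("divergence cleaning did not converge", call. = FALSE)
}

apply_noise <- function(lay, rate) {
  if (rate <= 0) return(lay)
  idx <- which(!lay$protected)
  hit <- idx[stats::runif(length(idx)) < rate]
  if (length(hit) > 0) {
    lay$chars[hit] <- vapply(lay$chars[hit], function(cur)
      sample(setdiff(AA20, cur), 1L), character(1))
  }
  lay
}

#' Generate one labeled synthetic archetype protein
#'
#' Deterministically (given `seed`) assembles a protein of the requested
#' architecture together with exact machine-readable ground truth. At zero
#' substitution rate, scanning the sequence recovers precisely the planted
#' loops, motifs and domains; the noise process never mutates the
#' constrained positions (coordinating residues, post--Z residue, motif
#' anchors, NAF tripeptide), so planted signals stay anchored while their
#' context degrades.
#'
#' @param family One of `r paste(ARCHETYPE_FAMILIES, collapse = ", ")`.
#' @param substitution_rate Fraction in [0, 1) of unconstrained positions
#'   substituted (each substituted position receives a uniformly drawn
#'   different residue).
#' @param seed Integer RNG seed.
#' @param species Species tag for the record.
#' @param id Record id; default is a content hash that carries no family
#'   information.
#' @param spacer12 EF1-EF2 spacer length for sensor families. Defaults to
#'   the invariant plant value of 23; for `CBL_NONPLANT` it is drawn
#'   uniformly from 19--24.
#' @param decoy_length Length of a `DECOY` protein (default 300).
#' @param divergence Within-family paralog divergence rate in [0, 1). When
#'   positive, the cleaned base sequence receives an extra round of
#'   substitutions (driven by `divergence_seed`) with any substitution that
#'   would corrupt the ground truth reverted. [generate_proteome()] uses
#'   this to emit same-species paralog groups as near copies of one base
#'   archetype, the sequence signature of intraspecific gene amplification.
#' @param divergence_seed Seed for the divergence round (default
#'   `seed + 1`).
#' @param config A [screen_config()] list shared with the detectors, so
#'   generator and scanner never disagree on thresholds.
#' @return List with `record` (one-row protein-set data.frame) and `truth`
#'   (list: `family`, `ef1_template`, `loops` data.frame of 0-based
#'   half-open coordinates, `spacers`, motif fields, `naf`, `kinase_core`).
#' @export
#' @examples
#' arch <- generate_archetype("CBL_PLANT", substitution_rate = 0, seed = 1)
#' scan_ef_hands(arch$record)$template
generate_archetype <- function(family, substitution_rate = 0, seed = 1L,
                               species = "unknown", id = NULL,
                               spacer12 = NULL, decoy_length = 300L,
                               divergence = 0, divergence_seed = seed + 1L,
                               config = screen_config()) {
  family <- match.arg(family, ARCHETYPE_FAMILIES)
  stopifnot(substitution_rate >= 0, substitution_rate < 1,
            divergence >= 0, divergence < 1)
  built <- with_seed(seed, {
    noise_seed <- sample.int(.Machine$integer.max - 1L, 1L)
    if (family == "DECOY") {
      lay <- list(chars = draw_bg(decoy_length),
                  random = rep(TRUE, decoy_length),
                  protected = rep(FALSE, decoy_length),
                  truth = list(family = "DECOY",
                               ef1_template = NA_character_, loops = NULL,
                               spacers = integer(0), myristoylation = FALSE,
                               cys3 = FALSE, fpsf_position = NA_integer_,
                               naf = NULL, kinase_core = NULL))
    } else if (family %in% c("CIPK", "KINASE_NO_NAF")) {
      lay <- clean_layout(kinase_layout(family), family, config)
    } else {
      sp12 <- spacer12 %||%
        (if (family == "CBL_NONPLANT") sample(19:24, 1L) else 23L)
      if (sp12 < 15L) stop("spacer12 must be at least 15", call. = FALSE)
      lay <- clean_layout(sensor_layout(family, as.integer(sp12)),
                          family, config)
      # emit-time self-check: every planted loop clears the shared threshold
      seqstr <- paste(lay$chars, collapse = "")
      for (i in seq_len(nrow(lay$truth$loops))) {
        w <- substr(seqstr, lay$truth$loops$start[i] + 1L,
                    lay$truth$loops$end[i])
        if (score_loop(w, lay$truth$loops$template[i], config) <
            config$efhand$threshold)
          stop("internal error: planted loop below threshold", call. = FALSE)
      }
    }
    list(lay = lay, noise_seed = noise_seed)
  })
  lay <- built$lay
  if (divergence > 0 && family != "DECOY")
    lay <- with_seed(divergence_seed, diverge_layout(lay, divergence, config))
  if (substitution_rate > 0)
    lay <- with_seed(built$noise_seed, apply_noise(lay, substitution_rate))
  sequence <- paste(lay$chars, collapse = "")
  rec_id <- id %||% paste0("S", fnv1a_hash(paste(seed, family, sequence)))
  list(record = data.frame(id = rec_id, species = species,
                           sequence = sequence, description = "",
                           stringsAsFactors = FALSE),
       truth = lay$truth)
}

#' Generate a labeled synthetic proteome
#'
#' Emits a FASTA file containing the requested archetype counts plus
#' unrelated decoy proteins of uniform background composition, in shuffled
#' order with content-hash ids, so neither record order nor identifiers leak
#' the labels. Ground truth lives only in the returned table.
#'
#' @param specs List of `list(family =, count =, substitution_rate =,
#'   divergence =)` entries (rate defaults to 0, divergence to 0.03). All
#'   copies requested by one entry are emitted as divergent near copies of
#'   a single base archetype, so same-species paralog groups carry the
#'   sequence signature of recent gene duplication that the
#'   amplification detector looks for; copies from different entries (or
#'   different proteome seeds) are unrelated in their seeded positions.
#' @param n_decoys Number of decoy proteins.
#' @param decoy_length_range Inclusive integer range of decoy lengths.
#' @param seed Integer RNG seed; output is byte-identical for identical
#'   inputs.
#' @param path FASTA output path.
#' @param species Species tag applied to every record.
#' @param config A [screen_config()] list.
#' @return List: `path`, `records` (protein-set data.frame), `truth`
#'   (data.frame with id, species, family, ef1_template, spacer12,
#'   n_loops, naf_present), `details` (per-id full truth lists).
#' @export
generate_proteome <- function(specs, n_decoys = 0L,
                              decoy_length_range = c(250L, 350L),
                              seed = 1L, path = tempfile(fileext = ".fasta"),
                              species = "unknown",
                              config = screen_config()) {
  stopifnot(all(vapply(specs, function(s) s$count >= 0, logical(1))))
  plan <- do.call(rbind, lapply(seq_along(specs), function(g) {
    s <- specs[[g]]
    if (s$count > 0)
      data.frame(family = rep(s$family, s$count), group = g,
                 rate = s$substitution_rate %||% 0,
                 divergence = s$divergence %||% 0.03,
                 stringsAsFactors = FALSE)
  }))
  empty_plan <- data.frame(family = character(0), group = integer(0),
                           rate = numeric(0), divergence = numeric(0))
  if (n_decoys > 0) {
    plan <- rbind(plan %||% empty_plan,
                  data.frame(family = rep("DECOY", n_decoys), group = 0L,
                             rate = 0, divergence = 0))
  }
  if (is.null(plan) || nrow(plan) == 0)
    stop("empty proteome specification", call. = FALSE)

  with_seed(seed, {
    n <- nrow(plan)
    # one base seed per spec entry (paralog group), one per-copy seed for
    # divergence / decoy content
    group_seeds <- sample.int(.Machine$integer.max - 1L,
                              max(1L, length(specs)))
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
    decoy_lens <- sample(decoy_length_range[1]:decoy_length_range[2], n,
                         replace = TRUE)
    order_shuffled <- sample.int(n)
    gens <- lapply(seq_len(n), function(k) {
      if (plan$family[k] == "DECOY") {
        generate_archetype("DECOY", seed = sub_seeds[k], species = species,
                           decoy_length = decoy_lens[k], config = config)
      } else {
        generate_archetype(plan$family[k], substitution_rate = plan$rate[k],
                           seed = group_seeds[plan$group[k]],
                           species = species,
                           divergence = plan$divergence[k],
                           divergence_seed = sub_seeds[k], config = config)
      }
    })
    gens <- gens[order_shuffled]
    ids <- vapply(seq_len(n), function(k)
      paste0("S", fnv1a_hash(paste(seed, k, "id"))), character(1))
    while (anyDuplicated(ids))
      ids[duplicated(ids)] <- paste0(ids[duplicated(ids)], "b")
    records <- do.call(rbind, lapply(gens, `[[`, "record"))
    records$id <- ids
    details <- lapply(gens, `[[`, "truth")
    names(details) <- ids
    truth <- data.frame(
      id = ids, species = species,
      family = vapply(details, `[[`, character(1), "family"),
      ef1_template = vapply(details, `[[`, character(1), "ef1_template"),
      spacer12 = vapply(details, function(t)
        if (length(t$spacers) >= 1) t$spacers[1] else NA_integer_, integer(1)),
      n_loops = vapply(details, function(t)
        if (is.null(t$loops)) 0L else nrow(t$loops), integer(1)),
      naf_present = vapply(details, function(t) !is.null(t$naf), logical(1)),
      stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    write_fasta(records, path)
    list(path = path, records = records, truth = truth, details = details)
  })
}

#' Generate a NAF seed alignment from the synthetic CIPK family
#'
#' Extracts the 21-residue NAF window from `n` CIPK archetypes generated at
#' the given substitution rate. This is how the packaged default seed
#' alignment (`inst/extdata/naf_seed_synthetic.txt`) was produced; it is a
#' synthetic stand-in, and real-proteome screens should use a curated
#' alignment instead.
#'
#' @param n Number of rows.
#' @param substitution_rate Noise rate applied to non-tripeptide positions.
#' @param seed Integer RNG seed.
#' @param config A [screen_config()] list.
#' @return Character vector of `n` 21-residue strings.
#' @export
generate_naf_seed_alignment <- function(n = 20L, substitution_rate = 0.1,
                                        seed = 7L,
                                        config = screen_config()) {
  with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
    vapply(seq_len(n), function(k) {
      g <- generate_archetype("CIPK", substitution_rate = substitution_rate,
                              seed = sub_seeds[k], config = config)
      substr(g$record$sequence, g$truth$naf$start + 1L, g$truth$naf$end)
    }, character(1))
  })
}
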