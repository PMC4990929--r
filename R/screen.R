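# Full multilevel screen: local-alignment prefilter -> EF-hand scan ->
# sensor classification (sensor arm), kinase-core + NAF detection on the
# whole proteome (kinase arm), pooled CBL candidates -> distance matrix ->
# neighbor joining -> intraspecific-amplification flags, and the per-species
# inventory.

#' Default prefilter query
#'
#' The zero-noise plant-CBL archetype used as the default query for the
#' local-alignment prefilter, playing the role a canonical plant CBL plays
#' in a homology screen of real proteomes.
#'
#' @param config A [screen_config()] list.
#' @return One-row protein-set data.frame.
#' @export
default_prefilter_query <- function(config = screen_config()) {
  generate_archetype("CBL_PLANT", substitution_rate = 0, seed = 20L,
                     id = "query_plant_cbl", config = config)$record
}

#' Prefilter a proteome by local alignment to a query
#'
#' Retains the records whose best Smith-Waterman local-alignment score
#' against the query reaches `threshold_frac` of the query self-score
#' (default 0.25), preserving input order. This replaces a database homology
#' search with an in-package alignment filter; the fraction-of-self-score
#' threshold avoids any database-size model.
#'
#' @param query One-row protein-set data.frame or sequence string.
#' @param proteome Protein-set data.frame (non-empty).
#' @param config A [screen_config()] list; uses `config$prefilter` and
#'   `config$align`.
#' @return The retained subset of `proteome`, order preserved.
#' @export
prefilter_candidates <- function(query, proteome, config = screen_config()) {
  qseq <- if (is.data.frame(query)) query$sequence[1] else query
  stopifnot(is.data.frame(proteome), nrow(proteome) > 0)
  self_score <- local_align_score(qseq, qseq, config)
  cutoff <- config$prefilter$threshold_frac * self_score
  keep <- vapply(proteome$sequence, function(s)
    local_align_score(qseq, s, config) >= cutoff, logical(1),
    USE.NAMES = FALSE)
  proteome[keep, , drop = FALSE]
}

annotate_proteome <- function(records, query, pssm, config) {
  retained <- prefilter_candidates(query, records, config)
  in_sensor_arm <- records$id %in% retained$id

  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    row <- data.frame(
      id = rec$id, species = rec$species, family = NA_character_,
      n_ef_hands = NA_integer_, ef1_template = NA_character_,
      ef1_length = NA_integer_, spacer12 = NA_integer_,
      x_residue = NA_character_, post_minus_z = NA_character_,
      myristoylation = NA, cys3 = NA, fpsf_position = NA_integer_,
      ef1_score = NA_real_, naf_present = FALSE, naf_score = NA_real_,
      kinase_core = FALSE, verdict = NA_character_,
      stringsAsFactors = FALSE)
    if (in_sensor_arm[i]) {
      hits <- scan_ef_hands(rec, config)
      cls <- classify_sensor(rec, hits, config)
      row$family <- cls$family
      row$n_ef_hands <- cls$n_ef_hands
      row$ef1_template <- cls$ef1_template
      row$ef1_length <- if (nrow(hits) >= 1)
        hits$loop_end[1] - hits$loop_start[1] else NA_integer_
      row$spacer12 <- cls$spacer12
      row$x_residue <- cls$x_residue
      row$post_minus_z <- cls$post_minus_z
      row$myristoylation <- cls$lipid$myristoylation
      row$cys3 <- cls$lipid$cys3
      row$fpsf_position <- cls$fpsf_position
      row$ef1_score <- if (nrow(hits) >= 1) hits$score[1] else NA_real_
    }
    kc <- call_kinase(rec, pssm, config)
    row$kinase_core <- kc$has_kinase_core
    row$naf_present <- nrow(kc$naf_hits) >= 1
    row$naf_score <- if (nrow(kc$naf_hits) >= 1) kc$naf_hits$pssm_score[1]
      else NA_real_
    row$verdict <- kc$verdict
    row
  })
  do.call(rbind, rows)
}

CBL_FAMILIES <- c("CBL_PLANT", "CBL_NONPLANT", "CBL_STRAMENOPILE",
                  "CBL_EXTENDED", "CBL_DEGENERATE")

build_inventory <- function(annotations, amplification) {
  species <- sort(unique(annotations$species))
  rows <- lapply(species, function(sp) {
    a <- annotations[annotations$species == sp, , drop = FALSE]
    cnt <- function(fam) sum(!is.na(a$family) & a$family == fam)
    data.frame(
      species = sp,
      n_CAM_LIKE = cnt("CAM_LIKE"),
      n_CNB_NCS_LIKE = cnt("CNB_NCS_LIKE"),
      n_CBL_PLANT = cnt("CBL_PLANT"),
      n_CBL_NONPLANT = cnt("CBL_NONPLANT"),
      n_CBL_STRAMENOPILE = cnt("CBL_STRAMENOPILE"),
      n_CBL_EXTENDED = cnt("CBL_EXTENDED"),
      n_CBL_DEGENERATE = cnt("CBL_DEGENERATE"),
      n_CBL_total = sum(!is.na(a$family) & a$family %in% CBL_FAMILIES),
      n_CIPK = sum(a$verdict == "CIPK"),
      n_KINASE_NO_NAF = sum(a$verdict == "KINASE_NO_NAF"),
      amplification = sp %in% amplification$species,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full multilevel screen
#'
#' For each proteome: prefilter against the query, scan retained proteins
#' for EF-hands and classify them (sensor arm); run the kinase-core and
#' NAF-domain screen on the complete proteome (kinase arm -- kinases do not
#' resemble the sensor query, so they must not pass through its prefilter).
#' CBL-classified proteins from all species are then pooled into a
#' distance matrix and a neighbor-joining tree on which monospecific clades
#' flag intraspecific gene amplification. Identical inputs and
#' configuration give byte-identical outputs.
#'
#' @param proteomes Named character vector or list mapping species name to
#'   FASTA path (may be empty), or a data.frame with columns `species`,
#'   `path`.
#' @param config A [screen_config()] list.
#' @param query Prefilter query record; default [default_prefilter_query()].
#' @param pssm NAF PSSM; default [default_naf_pssm()].
#' @param out_dir Optional output directory; when given, writes
#'   `annotations.tsv`, `inventory.tsv`, `amplification.tsv`,
#'   `cbl_tree.nwk` (when a tree was built) and `run_log.tsv`, each stamped
#'   with the configuration hash and seed.
#' @return List of class `screen_result`: `inventory`, `annotations`,
#'   `tree` (phylo or NULL), `amplification`, `log` (per-species status),
#'   `config_hash`, `seed`.
#' @export
run_screen <- function(proteomes, config = screen_config(),
                       query = default_prefilter_query(config),
                       pssm = default_naf_pssm(config), out_dir = NULL) {
  if (is.data.frame(proteomes)) {
    paths <- stats::setNames(proteomes$path, proteomes$species)
  } else {
    paths <- unlist(proteomes)
  }
  chash <- config_hash(config)
  seed <- config$seed %||% NA_integer_

  ann_list <- list()
  log_rows <- list()
  for (sp in names(paths)) {
    status <- tryCatch({
      records <- read_fasta(paths[[sp]], species_hint = sp)
      records$species <- sp
      ann_list[[sp]] <- annotate_proteome(records, query, pssm, config)
      "ok"
    }, error = function(e) paste("error:", conditionMessage(e)))
    log_rows[[sp]] <- data.frame(species = sp, path = paths[[sp]],
                                 status = status, stringsAsFactors = FALSE)
  }
  annotations <- if (length(ann_list) > 0) do.call(rbind, ann_list) else
    data.frame(id = character(0), species = character(0),
               family = character(0), verdict = character(0),
               stringsAsFactors = FALSE)
  rownames(annotations) <- NULL
  run_log <- if (length(log_rows) > 0) do.call(rbind, log_rows) else
    data.frame(species = character(0), path = character(0),
               status = character(0), stringsAsFactors = FALSE)
  rownames(run_log) <- NULL

  cbl <- annotations[!is.na(annotations$family) &
                       annotations$family %in% CBL_FAMILIES, , drop = FALSE]
  tree <- NULL
  amplification <- data.frame(species = character(0), n_genes = integer(0),
                              leaf_ids = character(0),
                              stringsAsFactors = FALSE)
  if (nrow(cbl) >= 3) {
    cbl_records <- do.call(rbind, lapply(names(ann_list), function(sp) {
      recs <- read_fasta(paths[[sp]], species_hint = sp)
      recs$species <- sp
      recs[recs$id %in% cbl$id[cbl$species == sp], , drop = FALSE]
    }))
    dm <- distance_matrix(cbl_records, config)
    tree <- nj_tree(dm)
    species_of <- stats::setNames(cbl_records$species, cbl_records$id)
    amplification <- detect_amplification(tree, species_of)
  }

  inventory <- if (nrow(annotations) > 0)
    build_inventory(annotations, amplification) else
    data.frame(species = character(0), n_CBL_total = integer(0),
               n_CIPK = integer(0), stringsAsFactors = FALSE)

  result <- structure(list(inventory = inventory, annotations = annotations,
                           tree = tree, amplification = amplification,
                           log = run_log, config_hash = chash, seed = seed),
                      class = "screen_result")
  if (!is.null(out_dir)) write_screen_outputs(result, out_dir)
  result
}

write_screen_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- c(config_hash = result$config_hash, seed = result$seed)
  write_annotations(result$annotations, file.path(out_dir, "annotations.tsv"),
                    format = "tsv", header = stamp)
  write_annotations(result$inventory, file.path(out_dir, "inventory.tsv"),
                    format = "tsv", header = stamp)
  write_annotations(result$amplification,
                    file.path(out_dir, "amplification.tsv"),
                    format = "tsv", header = stamp)
  write_annotations(result$log, file.path(out_dir, "run_log.tsv"),
                    format = "tsv", header = stamp)
  if (!is.null(result$tree))
    write_newick(result$tree, file.path(out_dir, "cbl_tree.nwk"))
  invisible(out_dir)
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Multilevel CBL/CIPK screen\n")
  cat(sprintf("  %d species, %d proteins annotated\n",
              nrow(x$inventory), nrow(x$annotations)))
  if (nrow(x$inventory) > 0) print(x$inventory, row.names = FALSE)
  if (nrow(x$amplification) > 0) {
    cat("  intraspecific amplification flagged for:",
        paste(x$amplification$species, collapse = ", "), "\n")
  }
  invisible(x)
}
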