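# Distance-based grouping of candidate sensors and detection of
# intraspecific gene amplification (paralog expansion). Pairwise global
# alignments give identity-based distances; a neighbor-joining tree built
# from them supplies the clade structure on which a monospecific-clade test
# flags species whose paralogs group together.

blosum_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Global pairwise alignment score and identity
#'
#' Needleman-Wunsch global alignment with a standard substitution matrix
#' (default BLOSUM62) and affine gaps (open 11, extend 1; a gap of length L
#' costs `open + L * extend`). Identity is matches divided by alignment
#' columns, gap columns counting as non-matches.
#'
#' @param a,b Non-empty sequence strings.
#' @param config A [screen_config()] list; uses `config$align`.
#' @return List with `score` and `identity` (fraction in [0, 1]).
#' @export
#' @examples
#' global_align("MKV", "MRV")$score  # 5 + 2 + 4 = 11
global_align <- function(a, b, config = screen_config()) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  al <- config$align
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = blosum_matrix(al$matrix),
    gapOpening = al$gap_open, gapExtension = al$gap_extend)
  ncol <- nchar(as.character(Biostrings::alignedPattern(aln)))
  list(score = Biostrings::score(aln),
       identity = Biostrings::nmatch(aln) / ncol)
}

# Best local (Smith-Waterman) alignment score; used by the screen prefilter.
local_align_score <- function(a, b, config = screen_config()) {
  al <- config$align
  Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = blosum_matrix(al$matrix),
    gapOpening = al$gap_open, gapExtension = al$gap_extend,
    scoreOnly = TRUE)
}

#' Pairwise distance matrix from global alignments
#'
#' `d(i, j) = 1 - identity(i, j)`, computed once per pair, symmetric with a
#' zero diagonal. With `config$align$poisson_correct = TRUE` distances are
#' instead `-log(identity)` (Poisson-corrected, clamped to be finite).
#'
#' @param records Protein-set data.frame with at least 2 rows and unique ids.
#' @param config A [screen_config()] list.
#' @return List of class `distance_matrix`: `labels` (record ids) and `d`
#'   (symmetric numeric matrix).
#' @export
distance_matrix <- function(records, config = screen_config()) {
  stopifnot(is.data.frame(records), nrow(records) >= 2)
  if (anyDuplicated(records$id))
    stop("duplicate record ids in distance_matrix input", call. = FALSE)
  n <- nrow(records)
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ident <- global_align(records$sequence[i], records$sequence[j],
                            config)$identity
      dij <- if (isTRUE(config$align$poisson_correct))
        -log(max(ident, 1e-6)) else 1 - ident
      d[i, j] <- d[j, i] <- dij
    }
  }
  structure(list(labels = records$id, d = d), class = "distance_matrix")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with deterministic tie-breaking (among
#' equally good joins, the pair whose smallest member labels sort first is
#' taken; an internal node carries the smallest leaf label of its cluster).
#' Negative branch lengths are clamped to zero with the deficit transferred
#' to the sibling branch, preserving the joined pair's total. The result is
#' exact on additive matrices: leaf-to-leaf path lengths reproduce the
#' input.
#'
#' @param dm A `distance_matrix` (or a plain symmetric matrix with
#'   dimnames), n >= 3.
#' @return An unrooted `ape` `phylo` tree with branch lengths.
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "distance_matrix")) dm$d else as.matrix(dm)
  labels <- if (inherits(dm, "distance_matrix")) dm$labels else rownames(d)
  n <- nrow(d)
  if (n < 3) stop("neighbor joining requires at least 3 leaves", call. = FALSE)
  stopifnot(isSymmetric(unname(d)), all(is.finite(d)))

  fmt <- function(x) sprintf("%.17g", max(x, 0))
  nwk <- labels                 # newick fragment per active node
  key <- labels                 # smallest leaf label in each cluster
  act <- seq_len(n)
  D <- d

  while (length(act) > 3) {
    m <- length(act)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    ties <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    ties <- ties[ties[, 1] < ties[, 2], , drop = FALSE]
    pk <- apply(ties, 1, function(ij) {
      ks <- sort(c(key[ij[1]], key[ij[2]]))
      paste(ks, collapse = "\x1f")
    })
    best <- ties[order(pk)[1], ]
    i <- best[[1]]; j <- best[[2]]

    dij <- D[i, j]
    bi <- 0.5 * dij + (r[i] - r[j]) / (2 * (m - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(bi), nwk[j], fmt(bj))
    new_key <- min(key[i], key[j])

    du <- 0.5 * (D[i, ] + D[j, ] - dij)
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    key <- c(key[keep], new_key)
    act <- seq_len(m - 1)
  }

  # Final three clusters join at one internal node (three-point formulas).
  b1 <- 0.5 * (D[1, 2] + D[1, 3] - D[2, 3])
  b2 <- 0.5 * (D[1, 2] + D[2, 3] - D[1, 3])
  b3 <- 0.5 * (D[1, 3] + D[2, 3] - D[1, 2])
  text <- sprintf("(%s:%s,%s:%s,%s:%s);",
                  nwk[1], fmt(b1), nwk[2], fmt(b2), nwk[3], fmt(b3))
  ape::read.tree(text = text)
}

#' Flag intraspecific gene amplification
#'
#' A species with two or more leaves is flagged when some edge of the
#' unrooted tree separates exactly that species' leaves from everything
#' else, i.e. its paralogs form a monospecific clade -- the signature of
#' gene-family expansion by duplication within one species.
#'
#' @param tree An `ape` `phylo` tree.
#' @param species_of Named character vector mapping every leaf label to a
#'   species.
#' @return data.frame with columns `species`, `n_genes`, `leaf_ids`
#'   (comma-separated), sorted by species; zero rows when nothing is
#'   flagged.
#' @export
detect_amplification <- function(tree, species_of) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  unmapped <- setdiff(tips, names(species_of))
  if (length(unmapped) > 0)
    stop("unmapped leaf: ", unmapped[1], call. = FALSE)
  sp <- species_of[tips]

  ntip <- length(tips)
  # Descendant tip sets per edge (child side), via one postorder pass.
  desc <- vector("list", ntip + tree$Nnode)
  for (t in seq_len(ntip)) desc[[t]] <- t
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(po))) {
    parent <- po[k, 1]; child <- po[k, 2]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  sides <- lapply(seq_len(nrow(po)), function(k) sort(desc[[po[k, 2]]]))

  out <- list()
  for (s in sort(unique(sp))) {
    leaves <- sort(unname(which(sp == s)))
    if (length(leaves) < 2) next
    comp <- setdiff(seq_len(ntip), leaves)
    hit <- any(vapply(sides, function(side) {
      identical(side, leaves) || identical(sort(setdiff(seq_len(ntip), side)),
                                           leaves)
    }, logical(1)))
    if (hit)
      out[[s]] <- data.frame(species = s, n_genes = length(leaves),
                             leaf_ids = paste(tips[leaves], collapse = ","),
                             stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(species = character(0), n_genes = integer(0),
                      leaf_ids = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
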