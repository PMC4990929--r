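# Independent oracles, written from the stated rules rather than by calling
# package internals, so that scanner/alignment/PSSM results can be checked
# against a second implementation.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n) paste(sample(AA, n, replace = TRUE),
                                    collapse = "")

ORACLE_TEMPLATES <- list(
  L12 = list(len = 12, ins = 0), L14 = list(len = 14, ins = 2),
  L15 = list(len = 15, ins = 3), L19 = list(len = 19, ins = 7))

# Term-by-term recomputation of the loop score.
naive_score_loop <- function(window, tname) {
  t <- ORACLE_TEMPLATES[[tname]]
  ch <- strsplit(window, "")[[1]]
  stopifnot(length(ch) == t$len)
  x <- ch[1]; y <- ch[3 + t$ins]; z <- ch[5 + t$ins]
  mx <- ch[9 + t$ins]; mz <- ch[t$len]
  term <- 0
  term <- term + if (mz == "E") 3 else if (mz == "D") 1.5 else if (mz == "X") 0 else -5
  term <- term +
    if (x %in% c("D", "S")) 2 else if (x == "N") 1 else if (x == "X") 0 else
      if (tname == "L15" && x == "A") 1 else
        if (tname == "L15" && x == "L") 1.5 else -2
  coordset <- c("D", "N", "S", "T", "E", "G", "Q")
  term <- term + (y %in% coordset) + (z %in% coordset)
  term <- term + 0.5 * (mx %in% c("D", "N", "S", "T", "E", "G"))
  if (tname == "L15") {
    ins_region <- ch[2:(2 + t$ins)]          # between X and Y
    term <- term + any(ins_region == "G")
    mid <- paste(ch[5:11], collapse = "")    # loop offsets 4..10, 0-based
    term <- term + grepl("Q[HN]E", mid)
  }
  term
}

# Exhaustive enumeration of all (position, template) windows followed by the
# same greedy resolution rule: score desc, start asc, longer template first.
brute_force_scan <- function(sequence, threshold = 4, max_hits = 6) {
  n <- nchar(sequence)
  cand <- list()
  for (tname in names(ORACLE_TEMPLATES)) {
    len <- ORACLE_TEMPLATES[[tname]]$len
    if (n < len) next
    for (s0 in 0:(n - len)) {
      w <- substr(sequence, s0 + 1, s0 + len)
      sc <- naive_score_loop(w, tname)
      if (sc >= threshold)
        cand[[length(cand) + 1]] <- data.frame(
          start = s0, len = len, template = tname, score = sc)
    }
  }
  if (length(cand) == 0)
    return(data.frame(start = integer(0), len = integer(0),
                      template = character(0), score = numeric(0)))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score, cand$start, -cand$len, cand$template), ,
               drop = FALSE]
  sel <- integer(0)
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- s + cand$len[i]
    if (length(sel) && any(s < cand$start[sel] + cand$len[sel] &
                             cand$start[sel] < e)) next
    sel <- c(sel, i)
    if (length(sel) >= max_hits) break
  }
  out <- cand[sel, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Gotoh affine-gap dynamic programming. A gap of length L costs
# open + L * ext. type "global" (Needleman-Wunsch) or "local"
# (Smith-Waterman, score only).
dp_align_score <- function(a, b, type = "global", open = 11, ext = 1) {
  sm <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    get("BLOSUM62", envir = e)
  })
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in b (A aligned to gap)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in a
  local_mode <- type == "local"
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- if (local_mode) NEG else -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- if (local_mode) NEG else -(open + j * ext)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sm[A[i], B[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j],
                             if (local_mode) 0 else NEG) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
      if (local_mode) best <- max(best, M[i + 1, j + 1])
    }
  }
  if (local_mode) best else max(M[n + 1, m + 1], X[n + 1, m + 1],
                                Y[n + 1, m + 1])
}

# PSSM counting oracle.
naive_pssm <- function(rows, pc) {
  n <- length(rows)
  mat <- matrix(0, 21, 20, dimnames = list(NULL, AA))
  for (r in rows) {
    ch <- strsplit(r, "")[[1]]
    for (p in 1:21) if (ch[p] %in% AA) mat[p, ch[p]] <- mat[p, ch[p]] + 1
  }
  log2((mat + pc) / (n + 20 * pc)) - log2(1 / 20)
}

# Monospecific-clade oracle built on ape::prop.part (clades of the rooted
# representation); a species is flagged iff its leaf set equals a clade or a
# clade complement.
bipartition_oracle <- function(tree, species_of) {
  tips <- tree$tip.label
  pp <- ape::prop.part(tree)
  clades <- lapply(pp, function(x) sort(x))
  clades <- c(clades, lapply(seq_along(tips), function(i) i))
  all_idx <- seq_along(tips)
  flagged <- character(0)
  for (s in sort(unique(species_of[tips]))) {
    leaves <- sort(unname(which(species_of[tips] == s)))
    if (length(leaves) < 2) next
    ok <- any(vapply(clades, function(cl)
      identical(cl, leaves) || identical(sort(setdiff(all_idx, cl)), leaves),
      logical(1)))
    if (ok) flagged <- c(flagged, s)
  }
  flagged
}

# Least-squares brute force over the three unrooted 4-leaf topologies.
# Returns the path-length matrix of the best-fitting tree.
brute_force_nj4 <- function(d) {
  labs <- rownames(d)
  splits <- list(c(1, 2), c(1, 3), c(1, 4))
  best <- NULL
  for (sp in splits) {
    pair1 <- sp; pair2 <- setdiff(1:4, sp)
    # branch parameters: e1..e4 external, m internal
    # path(i,j) = e_i + e_j (+ m if across the split)
    Amat <- NULL; bvec <- NULL
    for (i in 1:3) for (j in (i + 1):4) {
      row <- numeric(5); row[i] <- 1; row[j] <- 1
      across <- !(all(c(i, j) %in% pair1) || all(c(i, j) %in% pair2))
      row[5] <- as.numeric(across)
      Amat <- rbind(Amat, row); bvec <- c(bvec, d[i, j])
    }
    fit <- qr.solve(Amat, bvec)
    resid <- sum((Amat %*% fit - bvec)^2)
    if (is.null(best) || resid < best$resid)
      best <- list(resid = resid, A = Amat, fit = fit)
  }
  p <- best$A %*% best$fit
  out <- matrix(0, 4, 4, dimnames = list(labs, labs))
  k <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    k <- k + 1; out[i, j] <- out[j, i] <- p[k]
  }
  out
}
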