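make_pssm <- function() {
  build_naf_pssm(read_seed_alignment(
    system.file("extdata", "naf_seed_synthetic.txt", package = "cblscreen")))
}

test_that("kinase-core check needs HRD and DFG at catalytic spacing", {
  arch <- generate_archetype("CIPK", substitution_rate = 0, seed = 5)
  expect_true(detect_kinase_core(arch$record))

  set.seed(55)
  for (i in 1:20) {
    s <- random_protein(200)
    expect_equal(detect_kinase_core(s),
                 {
                   # direct substring oracle
                   hrd <- gregexpr("HRD", s, fixed = TRUE)[[1]]
                   dfg <- gregexpr("DFG", s, fixed = TRUE)[[1]]
                   any(hrd > 0) && any(dfg > 0) &&
                     any(outer(dfg, hrd + 3, "-") >= 10 &
                           outer(dfg, hrd + 3, "-") <= 60)
                 }, info = s)
  }
  # spacing bound: DFG far beyond the 60-residue limit
  s <- paste0("MAA", "HRD", strrep("K", 200), "DFG", "AA")
  expect_false(detect_kinase_core(s))
  s <- paste0("MAA", "HRD", strrep("K", 30), "DFG", "AA")
  expect_true(detect_kinase_core(s))
})

test_that("PSSM entries follow the smoothed log-odds closed form", {
  rows <- c(replicate(10, paste0("N", paste(sample(AA, 20, replace = TRUE),
                                            collapse = ""))))
  rows <- substr(rows, 1, 21)
  pssm <- build_naf_pssm(rows, pseudocount = 0.1)
  expect_equal(unname(pssm[1, "N"]), log2(10.1 / 12) - log2(0.05))

  # a uniform column with zero pseudocount scores zero for every residue
  uni <- vapply(1:20, function(i) paste(rep(AA[i], 21), collapse = ""),
                character(1))
  pssm0 <- build_naf_pssm(uni, pseudocount = 0)
  expect_true(all(abs(pssm0[1, ]) < 1e-12))

  expect_error(build_naf_pssm(c("NAF", "NAFNAF")), "21")
})

test_that("PSSM equals the counting oracle on random alignments", {
  set.seed(66)
  for (i in 1:50) {
    n <- sample(2:12, 1)
    pc <- sample(c(0.05, 0.1, 0.5, 1), 1)
    rows <- vapply(seq_len(n), function(k) random_protein(21), character(1))
    got <- build_naf_pssm(rows, pseudocount = pc)
    want <- naive_pssm(rows, pc)
    expect_equal(as.vector(unclass(got)[1:21, 1:20]), as.vector(want),
                 tolerance = 1e-12)
    expect_equal(colnames(got), colnames(want))
  }
})

test_that("NAF detection finds exactly one 21-residue window in a CIPK", {
  pssm <- make_pssm()
  arch <- generate_archetype("CIPK", substitution_rate = 0, seed = 8)
  hits <- detect_naf(arch$record, pssm)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$end - hits$start, 21L)
  expect_equal(hits$start, arch$truth$naf$start)
  expect_gt(hits$pssm_score, 0)
  expect_true(hits$invariants_satisfied)

  noNAF <- generate_archetype("KINASE_NO_NAF", substitution_rate = 0,
                              seed = 8)
  expect_equal(nrow(detect_naf(noNAF$record, pssm)), 0)
  expect_equal(nrow(detect_naf("MKNAFLV", pssm)), 0)   # shorter than 21
})

test_that("kinase verdicts separate CIPK, NAF-less kinase and non-kinase", {
  pssm <- make_pssm()
  expect_equal(call_kinase(generate_archetype("CIPK", seed = 2)$record,
                           pssm)$verdict, "CIPK")
  expect_equal(call_kinase(generate_archetype("KINASE_NO_NAF",
                                              seed = 2)$record,
                           pssm)$verdict, "KINASE_NO_NAF")
  expect_equal(call_kinase(generate_archetype("CBL_PLANT", seed = 2)$record,
                           pssm)$verdict, "NOT_KINASE")
})

test_that("deleting the NAF tripeptide flips CIPK to KINASE_NO_NAF", {
  pssm <- make_pssm()
  for (s in 1:20) {
    arch <- generate_archetype("CIPK", substitution_rate = 0, seed = s)
    expect_equal(call_kinase(arch$record, pssm)$verdict, "CIPK")
    tri0 <- arch$truth$naf$start + arch$truth$naf$tripeptide_offset
    seqstr <- arch$record$sequence
    expect_equal(substr(seqstr, tri0 + 1, tri0 + 3), "NAF")
    dnaf <- paste0(substr(seqstr, 1, tri0),
                   substr(seqstr, tri0 + 4, nchar(seqstr)))
    expect_equal(call_kinase(dnaf, pssm)$verdict, "KINASE_NO_NAF",
                 info = paste("seed", s))
  }
})

test_that("the column-consensus of a seed alignment dominates every row", {
  set.seed(88)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    rows <- vapply(seq_len(n), function(k) random_protein(21), character(1))
    pssm <- build_naf_pssm(rows, pseudocount = 0.1)
    consensus <- paste(AA[apply(unclass(pssm), 1, which.max)], collapse = "")
    score_of <- function(w) {
      ch <- strsplit(w, "")[[1]]
      sum(vapply(1:21, function(p) pssm[p, ch[p]], numeric(1)))
    }
    cs <- score_of(consensus)
    for (r in rows) expect_gte(cs, score_of(r))
  }
})
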