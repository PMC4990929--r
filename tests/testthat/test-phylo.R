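test_that("global alignment reproduces hand-computed scores and identities", {
  expect_equal(global_align("MGCF", "MGCF")$identity, 1.0)
  # no gap opened: s(M,M) + s(K,R) + s(V,V) = 5 + 2 + 4
  al <- global_align("MKV", "MRV")
  expect_equal(al$score, 11)
  expect_equal(al$identity, 2 / 3)
})

test_that("alignment score is symmetric", {
  set.seed(14)
  for (i in 1:15) {
    a <- random_protein(sample(8:60, 1)); b <- random_protein(sample(8:60, 1))
    expect_equal(global_align(a, b)$score, global_align(b, a)$score)
  }
})

test_that("distances are 1 - identity, symmetric, and order-equivariant", {
  recs <- data.frame(id = c("r1", "r2", "r3"), species = "s",
                     sequence = c("MGCFKL", "MGCFKL", "MGAWKL"),
                     stringsAsFactors = FALSE)
  dm <- distance_matrix(recs)
  expect_equal(dm$d["r1", "r2"], 0)
  expect_equal(dm$d["r1", "r3"],
               1 - global_align("MGCFKL", "MGAWKL")$identity)
  expect_true(isSymmetric(dm$d))
  expect_equal(unname(diag(dm$d)), c(0, 0, 0))

  perm <- recs[c(3, 1, 2), ]
  dmp <- distance_matrix(perm)
  expect_equal(dmp$d[recs$id, recs$id], dm$d[recs$id, recs$id])

  dup <- recs; dup$id <- c("a", "a", "b")
  expect_error(distance_matrix(dup), "duplicate")

  # element-wise oracle on random records
  set.seed(41)
  rr <- data.frame(id = paste0("q", 1:4), species = "s",
                   sequence = vapply(1:4, function(i)
                     random_protein(sample(20:60, 1)), character(1)),
                   stringsAsFactors = FALSE)
  dmr <- distance_matrix(rr)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(dmr$d[i, j],
                 1 - global_align(rr$sequence[i], rr$sequence[j])$identity)
  }
})

test_that("three leaves solve by the three-point formulas", {
  d <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  pl <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(pl, d, tolerance = 1e-12)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("the additive 4x4 example is reconstructed exactly", {
  labs <- c("A", "B", "C", "D")
  d <- matrix(c(0, 3, 7, 8,
                3, 0, 6, 7,
                7, 6, 0, 3,
                8, 7, 3, 0), 4, 4, dimnames = list(labs, labs))
  tr <- nj_tree(d)
  pl <- ape::cophenetic.phylo(tr)[labs, labs]
  expect_equal(pl, d, tolerance = 1e-9)
  # least-squares brute force over the three unrooted topologies agrees
  expect_equal(pl, brute_force_nj4(d), tolerance = 1e-9)
})

test_that("leaf label order does not change the reconstructed path lengths", {
  set.seed(19)
  rt <- ape::rtree(7, br = function(n) runif(n, 0.2, 1.5))
  d <- ape::cophenetic.phylo(rt)
  perm <- sample(rownames(d))
  t1 <- nj_tree(d)
  t2 <- nj_tree(d[perm, perm])
  labs <- rownames(d)
  expect_equal(ape::cophenetic.phylo(t1)[labs, labs],
               ape::cophenetic.phylo(t2)[labs, labs], tolerance = 1e-9)
})

test_that("amplification flags monospecific clades only", {
  # four paralogs of one species on one side of an edge
  tr <- ape::read.tree(
    text = "((p1:1,(p2:1,(p3:1,p4:1):1):1):2,(q1:1,q2:3):1,r1:1);")
  sp <- c(p1 = "tva", p2 = "tva", p3 = "tva", p4 = "tva",
          q1 = "ath", q2 = "ath", r1 = "ehx")
  amp <- detect_amplification(tr, sp)
  expect_equal(amp$species, c("ath", "tva"))
  expect_equal(amp$n_genes, c(2L, 4L))

  # every species has a single leaf
  tr1 <- ape::read.tree(text = "(a:1,b:1,c:1);")
  amp1 <- detect_amplification(tr1, c(a = "x", b = "y", c = "z"))
  expect_equal(nrow(amp1), 0)

  # same-species leaves separated on every edge cut are not flagged
  tr2 <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1,c1:1);")
  sp2 <- c(a1 = "A", b1 = "B", a2 = "A", b2 = "B", c1 = "C")
  expect_equal(nrow(detect_amplification(tr2, sp2)), 0)

  expect_error(detect_amplification(tr1, c(a = "x", b = "y")), "unmapped")
})

test_that("amplification equals the bipartition oracle on random trees", {
  set.seed(27)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    tr <- ape::rtree(n)
    tr$tip.label <- paste0("t", seq_len(n))
    sp <- setNames(sample(c("sp1", "sp2", "sp3"), n, replace = TRUE),
                   tr$tip.label)
    got <- detect_amplification(tr, sp)$species
    want <- bipartition_oracle(tr, sp)
    expect_equal(got, want, info = paste("case", i))
  }
})

test_that("neighbor joining is exact on simulated additive matrices", {
  set.seed(33)
  for (i in 1:30) {
    n <- sample(4:10, 1)
    rt <- ape::rtree(n, br = function(k) runif(k, 0.05, 2))
    d <- ape::cophenetic.phylo(rt)
    tr <- nj_tree(d)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
    expect_true(is.null(tr$edge.length) || all(tr$edge.length >= 0))
  }
})
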