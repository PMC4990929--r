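test_that("lipid motif detection follows the MGXXXS/T and Cys3 patterns", {
  m <- detect_lipid_motifs("MGAAASKKKKLVIWYR")
  expect_true(m$myristoylation); expect_false(m$cys3)

  m <- detect_lipid_motifs("MGCAASKKLVIWYRPQ")
  expect_true(m$myristoylation); expect_true(m$cys3)
  expect_equal(m$n_cys_nterm, 1L)

  m <- detect_lipid_motifs("AGAAASKK")
  expect_false(m$myristoylation)

  m <- detect_lipid_motifs("MGCCC")           # shorter than 6
  expect_false(m$myristoylation); expect_true(m$cys3)
  expect_equal(m$n_cys_nterm, 3L)
})

test_that("FPSF detection is windowed at the C-terminus", {
  set.seed(12)
  s <- paste0(random_protein(80), "KKFPSFVF")
  expect_equal(detect_fpsf(s), nchar(s) - 5L)

  far <- paste0("AAFPSF", strrep("K", 100))   # motif 100 residues upstream
  expect_true(is.na(detect_fpsf(far)))
  expect_equal(detect_fpsf(far, cterm_window = 110L), 3L)
  expect_true(is.na(detect_fpsf("MKKLVI")))

  # last in-window occurrence wins
  s2 <- paste0(strrep("K", 40), "FPSF", strrep("A", 10), "FPSF",
               strrep("V", 10))
  expect_equal(detect_fpsf(s2), 55L)
})

test_that("archetype families classify to their own labels", {
  cases <- list(
    CBL_PLANT = "CBL_PLANT", CAM_LIKE = "CAM_LIKE",
    CNB_NCS_LIKE = "CNB_NCS_LIKE", CBL_STRAMENOPILE = "CBL_STRAMENOPILE",
    CBL_EXTENDED = "CBL_EXTENDED", CBL_NONPLANT = "CBL_NONPLANT",
    CBL_DEGENERATE = "CBL_DEGENERATE")
  for (fam in names(cases)) {
    arch <- generate_archetype(fam, substitution_rate = 0, seed = 17)
    hits <- scan_ef_hands(arch$record)
    cls <- classify_sensor(arch$record, hits)
    expect_equal(cls$family, cases[[fam]], info = fam)
    expect_true(length(cls$evidence) > 0)
  }
})

test_that("plant verdict carries the full evidence set", {
  arch <- generate_archetype("CBL_PLANT", substitution_rate = 0, seed = 23)
  cls <- classify_sensor(arch$record, scan_ef_hands(arch$record))
  expect_equal(cls$ef1_template, "L14")
  expect_equal(cls$x_residue, "S")
  expect_equal(cls$post_minus_z, "F")
  expect_equal(cls$spacer12, 23L)
  expect_true(cls$lipid$cys3)
  expect_false(is.na(cls$fpsf_position))
})

test_that("a single EF-hand cannot be classified", {
  s <- paste0("MAAAA", "DKDGDGTITTKE", "LAAAA")
  hits <- scan_ef_hands(s)
  expect_equal(nrow(hits), 1)
  cls <- classify_sensor(s, hits)
  expect_equal(cls$family, "UNCLASSIFIED")
})

test_that("S-to-A exchange at X with one inserted residue flips a plant CBL
           to the degenerate class", {
  arch <- generate_archetype("CBL_PLANT", substitution_rate = 0, seed = 6)
  seqstr <- arch$record$sequence
  ef1 <- arch$truth$loops[1, ]
  expect_equal(substr(seqstr, ef1$start + 1, ef1$start + 1), "S")
  # replace the 14-residue EF1 by its 15-residue A-at-X counterpart:
  # X S->A plus a single extra residue inserted between X and Y
  mutated <- paste0(substr(seqstr, 1, ef1$start),
                    "AAAKADGDGTITTKE",
                    substr(seqstr, ef1$end + 1, nchar(seqstr)))
  hits <- scan_ef_hands(mutated)
  cls <- classify_sensor(mutated, hits)
  expect_equal(hits$template[1], "L15")
  expect_equal(cls$x_residue, "A")
  expect_equal(cls$family, "CBL_DEGENERATE")
})

test_that("classification is deterministic and assigns exactly one family", {
  set.seed(77)
  fams <- c("CBL_PLANT", "CBL_NONPLANT", "CAM_LIKE", "CBL_STRAMENOPILE")
  for (i in 1:12) {
    fam <- fams[1 + (i %% length(fams))]
    arch <- generate_archetype(fam, substitution_rate = 0.05, seed = 300 + i)
    hits <- scan_ef_hands(arch$record)
    c1 <- classify_sensor(arch$record, hits)
    c2 <- classify_sensor(arch$record, hits)
    expect_identical(c1, c2)
    expect_length(c1$family, 1)
    expect_true(c1$family %in% c("CAM_LIKE", "CNB_NCS_LIKE", "CBL_PLANT",
                                 "CBL_NONPLANT", "CBL_STRAMENOPILE",
                                 "CBL_EXTENDED", "CBL_DEGENERATE",
                                 "UNCLASSIFIED"))
    if (c1$family != "UNCLASSIFIED") expect_gt(length(c1$evidence), 0)
  }
})

test_that("unsorted or overlapping hit lists violate the contract", {
  arch <- generate_archetype("CBL_PLANT", substitution_rate = 0, seed = 2)
  hits <- scan_ef_hands(arch$record)
  expect_error(classify_sensor(arch$record, hits[c(3, 1, 2, 4), ]), "sorted")
  overlap <- hits
  overlap$loop_start[2] <- overlap$loop_end[1] - 2L
  expect_error(classify_sensor(arch$record, overlap), "overlap")
})
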