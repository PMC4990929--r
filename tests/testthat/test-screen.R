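test_that("prefilter keeps the query and drops unrelated decoys", {
  q <- default_prefilter_query()
  decoy <- data.frame(id = "g", species = "s",
                      sequence = strrep("G", 250), description = "",
                      stringsAsFactors = FALSE)
  prot <- rbind(q, decoy)
  kept <- prefilter_candidates(q, prot)
  expect_equal(kept$id, q$id)
})

test_that("prefilter equals the quadratic-time Smith-Waterman oracle", {
  set.seed(61)
  q <- default_prefilter_query()
  prot <- data.frame(
    id = paste0("r", 1:10), species = "s",
    sequence = c(vapply(1:7, function(i) random_protein(sample(80:200, 1)),
                        character(1)),
                 vapply(1:3, function(i)
                   generate_archetype("CBL_NONPLANT",
                                      seed = 400 + i)$record$sequence,
                   character(1))),
    stringsAsFactors = FALSE)
  kept <- prefilter_candidates(q, prot)
  self <- dp_align_score(q$sequence, q$sequence, type = "local")
  cutoff <- 0.25 * self
  want <- prot$id[vapply(prot$sequence, function(s)
    dp_align_score(q$sequence, s, type = "local") >= cutoff, logical(1))]
  expect_equal(kept$id, want)
})

test_that("no planted CBL is lost at the default prefilter threshold", {
  q <- default_prefilter_query()
  fams <- c("CBL_PLANT", "CBL_NONPLANT", "CBL_STRAMENOPILE",
            "CBL_EXTENDED", "CBL_DEGENERATE")
  for (s in 1:100) {
    fam <- fams[1 + (s %% length(fams))]
    rec <- generate_archetype(fam, substitution_rate = 0,
                              seed = 1000 + s)$record
    expect_equal(nrow(prefilter_candidates(q, rec)), 1,
                 info = paste(fam, s))
  }
})

test_that("the two-species bundle yields the expected inventory and
           amplification flag", {
  b <- make_bundle()
  res <- run_screen(b$paths)
  inv <- res$inventory
  expect_equal(inv$species, c("speciesA", "speciesB"))
  expect_equal(inv$n_CBL_total, c(1L, 4L))
  expect_equal(inv$n_CIPK, c(1L, 1L))
  expect_equal(inv$n_KINASE_NO_NAF, c(0L, 1L))
  expect_equal(inv$amplification, c(FALSE, TRUE))
  expect_equal(res$amplification$species, "speciesB")
  expect_equal(res$amplification$n_genes, 4L)
  expect_false(is.null(res$tree))
  expect_equal(length(res$tree$tip.label), 5)
})

test_that("inventory counts equal annotation rows (conservation check)", {
  b <- make_bundle()
  res <- run_screen(b$paths)
  ann <- res$annotations
  for (i in seq_len(nrow(res$inventory))) {
    sp <- res$inventory$species[i]
    a <- ann[ann$species == sp, ]
    expect_equal(res$inventory$n_CBL_total[i],
                 sum(a$family %in% c("CBL_PLANT", "CBL_NONPLANT",
                                     "CBL_STRAMENOPILE", "CBL_EXTENDED",
                                     "CBL_DEGENERATE"), na.rm = TRUE))
    expect_equal(res$inventory$n_CIPK[i], sum(a$verdict == "CIPK"))
    expect_equal(res$inventory$n_KINASE_NO_NAF[i],
                 sum(a$verdict == "KINASE_NO_NAF"))
  }
  expect_equal(sum(res$inventory$n_CBL_total),
               nrow(ann[!is.na(ann$family) &
                          grepl("^CBL_", ann$family), ]))
})

test_that("an empty proteome map screens to an empty inventory", {
  res <- run_screen(character(0))
  expect_equal(nrow(res$inventory), 0)
  expect_equal(nrow(res$annotations), 0)
  expect_null(res$tree)
})

test_that("a per-species failure is isolated and logged", {
  b <- make_bundle()
  paths <- c(b$paths, speciesC = file.path(tempdir(), "no_such_file.fasta"))
  res <- run_screen(paths)
  expect_equal(nrow(res$inventory), 2)   # A and B still screened
  expect_match(res$log$status[res$log$species == "speciesC"], "error")
  expect_equal(res$log$status[res$log$species != "speciesC"], c("ok", "ok"))
})

test_that("config files round trip through YAML and JSON", {
  skip_if_not_installed("yaml")
  cfg <- screen_config(efhand = list(threshold = 5.5), seed = 99L)
  tf <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(efhand = list(threshold = 5.5), seed = 99L), tf)
  got <- read_config(tf)
  expect_equal(got$efhand$threshold, 5.5)
  expect_equal(got$seed, 99L)
  expect_equal(got$naf$offset_min, screen_config()$naf$offset_min)

  tj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(prefilter = list(threshold_frac = 0.3)), tj,
                       auto_unbox = TRUE)
  expect_equal(read_config(tj)$prefilter$threshold_frac, 0.3)

  yaml::write_yaml(list(nonsense = 1), tf)
  expect_error(read_config(tf), "unknown config")
})
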