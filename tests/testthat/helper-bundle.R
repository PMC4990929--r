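# Two-species synthetic bundle used by the screen and acceptance tests:
# species A carries one plant CBL and one CIPK among decoys; species B four
# non-plant CBL paralogs, one CIPK and one NAF-less kinase among decoys.
make_bundle <- function(seedA = 11, seedB = 12) {
  fa <- tempfile(fileext = ".fasta"); fb <- tempfile(fileext = ".fasta")
  pa <- generate_proteome(
    list(list(family = "CBL_PLANT", count = 1),
         list(family = "CIPK", count = 1)),
    n_decoys = 3, seed = seedA, path = fa, species = "speciesA")
  pb <- generate_proteome(
    list(list(family = "CBL_NONPLANT", count = 4),
         list(family = "CIPK", count = 1),
         list(family = "KINASE_NO_NAF", count = 1)),
    n_decoys = 3, seed = seedB, path = fb, species = "speciesB")
  list(paths = c(speciesA = fa, speciesB = fb), pa = pa, pb = pb)
}
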