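# Internal constants and helpers shared across modules.

# The 20 standard residues; ambiguity code X is carried as a 21st symbol that
# scores 0 (neutral) at every motif position.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA21 <- c(AA20, "X")

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

encode_seq <- function(sequence) {
  idx <- match(seq_chars(sequence), AA21)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("invalid residue '%s' at position %d",
                 seq_chars(sequence)[bad], bad), call. = FALSE)
  }
  idx
}

#' Convert 0-based half-open coordinates to 1-based inclusive
#'
#' Internal coordinates are 0-based half-open throughout the package; every
#' serialized, human-facing coordinate is 1-based inclusive. The two
#' converters are inverse bijections on valid intervals.
#'
#' @param start0,end0 0-based half-open interval (`end0 > start0`).
#' @return Integer vector `c(start, end)`, 1-based inclusive.
#' @export
to_one_based <- function(start0, end0) {
  stopifnot(end0 > start0, start0 >= 0)
  c(start = as.integer(start0) + 1L, end = as.integer(end0))
}

#' @rdname to_one_based
#' @param start1,end1 1-based inclusive interval.
#' @return For `to_zero_based`, integer vector `c(start, end)`, 0-based
#'   half-open.
#' @export
to_zero_based <- function(start1, end1) {
  stopifnot(end1 >= start1, start1 >= 1)
  c(start = as.integer(start1) - 1L, end = as.integer(end1))
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits.
# Used to stamp outputs with a configuration fingerprint and to mint
# label-free record identifiers.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\x1f")))
  xor32 <- function(a, b) {
    # exact 32-bit XOR in doubles (bitwXor is limited to signed 32-bit)
    alo <- a %% 65536; ahi <- (a - alo) / 65536
    blo <- b %% 65536; bhi <- (b - blo) / 65536
    bitwXor(alo, blo) + bitwXor(ahi, bhi) * 65536
  }
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    # 32-bit modular multiply by the FNV prime 16777619, done in doubles
    # via 16-bit halves to stay exact.
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  hi <- (h - h %% 65536) / 65536
  sprintf("%04X%04X", as.integer(hi), as.integer(h %% 65536))
}

config_hash <- function(config) {
  fnv1a_hash(paste(deparse(config, control = "all"), collapse = "\n"))
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
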