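## Shared low-level helpers: reproducible local RNG, string/DNA utilities.

#' Evaluate code under a local RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the caller's RNG state, so
#' that simulation helpers are deterministic without clobbering the global
#' stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage integer seed from a master seed
#'
#' Stable integer hash of the master seed and any number of stage/index
#' keys. Always in `[1, 2^31 - 2]` so it is a valid R seed.
#'
#' @param seed Master integer seed.
#' @param ... Additional keys (integers or strings) identifying the stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483629  # largest prime below 2^31
  s <- as.double(seed %% m)
  for (k in list(...)) {
    v <- if (is.character(k)) sum(utf8ToInt(k) * seq_along(utf8ToInt(k))) else as.double(k)
    s <- (s * 69069 + v * 40503 + 12345) %% m
  }
  as.integer(s %% (m - 1L) + 1L)
}

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#' @param x Single character string over A/C/G/T/N (case-insensitive).
#' @return Reverse-complemented upper-case string.
#' @export
revcomp <- function(x) {
  stopifnot(length(x) == 1L)
  chartr("ACGTNacgtn", "TGCANtgcan",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""))
}

## Fast substring reverse complement for long sequences (vector-of-chars in,
## vector-of-chars out).
revcomp_chars <- function(ch) {
  rev(chartr("ACGTN", "TGCAN", ch))
}

#' Lexicographically smallest rotation of a motif
#' @param motif Short character string.
#' @return The canonical rotation.
#' @keywords internal
canonical_rotation <- function(motif) {
  n <- nchar(motif)
  if (n == 1L) return(motif)
  doubled <- paste0(motif, motif)
  rots <- vapply(seq_len(n), function(i) substr(doubled, i, i + n - 1L), "")
  min(rots)
}

## TRUE if the motif is a repetition of a shorter unit (i.e. non-primitive).
is_periodic_motif <- function(motif) {
  n <- nchar(motif)
  if (n == 1L) return(FALSE)
  for (d in seq_len(n - 1L)) {
    if (n %% d == 0L &&
        motif == strrep(substr(motif, 1L, d), n %/% d)) return(TRUE)
  }
  FALSE
}

## Random DNA string with a given GC fraction; plain character string.
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

## Split a string into a character vector of single characters.
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

## Write a data.frame as TSV (no quotes, no row names) -- the package's
## standard tabular output format.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
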