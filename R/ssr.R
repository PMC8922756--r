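## Perfect-microsatellite (SSR) scanner.
##
## Detects maximal perfect tandem repeats of primitive motifs of length
## 1-6 bp. Class-specific unit-count minima default to the standard plastome
## screening setup (10 mono, 5 di, 4 tri, 3 tetra/penta/hexa). A run of a
## periodic motif (e.g. "ATAT" = "AT" twice) is reported under its shortest
## period only; overlapping candidate runs of different motif lengths are
## resolved greedily, longest run (in bp) first.

DEFAULT_SSR_MINIMA <- c(`1` = 10L, `2` = 5L, `3` = 4L, `4` = 3L, `5` = 3L, `6` = 3L)

#' Scan a sequence for perfect SSRs
#'
#' @param seq A DNA string over A/C/G/T/N (a single character string).
#' @param min_units Named integer vector of minimum unit counts per motif
#'   length `1`..`6`.
#' @param sequence_id Identifier recorded in the output.
#' @return Data frame with one row per SSR: `sequence_id`, `motif`
#'   (canonical = lexicographically smallest rotation), `motif_length`,
#'   `unit_count`, `start` (0-based), `end` (half-open, covering the full
#'   units). Records are non-overlapping.
#' @export
find_ssrs <- function(seq, min_units = DEFAULT_SSR_MINIMA, sequence_id = "seq") {
  stopifnot(length(seq) == 1L, is.character(seq))
  ch <- str_chars(toupper(seq))
  n <- length(ch)
  cand <- list()
  for (m in 1:6) {
    if (n < m * min_units[[as.character(m)]]) next
    eq <- ch[seq_len(n - m)] == ch[(m + 1L):n] & ch[seq_len(n - m)] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run_len <- r$lengths[k] + m          # total bp of the tandem run
      units <- run_len %/% m
      if (units < min_units[[as.character(m)]]) next
      s0 <- starts[k]                      # 1-based start of the run
      motif <- paste(ch[s0:(s0 + m - 1L)], collapse = "")
      if (is_periodic_motif(motif)) next   # reported under the shorter period
      cand[[length(cand) + 1L]] <- data.frame(
        sequence_id = sequence_id,
        motif = canonical_rotation(motif),
        motif_length = m,
        unit_count = units,
        start = s0 - 1L,
        end = s0 - 1L + units * m,
        run_bp = run_len)
    }
  }
  empty <- data.frame(sequence_id = character(), motif = character(),
                      motif_length = integer(), unit_count = integer(),
                      start = integer(), end = integer())
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  ## Greedy non-overlap resolution: longest run first, then leftmost, then
  ## shortest motif.
  cand <- cand[order(-cand$run_bp, cand$start, cand$motif_length), ]
  keep <- logical(nrow(cand))
  taken_start <- integer(0); taken_end <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] < taken_end & cand$end[i] > taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, cand$start[i])
      taken_end <- c(taken_end, cand$end[i])
    }
  }
  out <- cand[keep, setdiff(names(cand), "run_bp"), drop = FALSE]
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}
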