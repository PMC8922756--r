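## Per-gene and sliding-window variability statistics.
##
## Nucleotide diversity follows the population-genetic definition used by
## DnaSP: the mean, over all unordered sequence pairs, of the proportion of
## differing sites among sites comparable in that pair (pairwise deletion of
## gaps and Ns). Segregating sites S count alignment columns with at least
## two distinct determinate states; PV = S / aligned length (gap columns
## included in the denominator).

VALID_STATES <- c("A", "C", "G", "T")

#' Nucleotide diversity (pi) of an alignment
#'
#' Mean pairwise difference per comparable site, with pairwise deletion of
#' gaps and ambiguous bases.
#'
#' @param aln A `gene_alignment` with at least two rows.
#' @return A single number; `NaN` with attribute `undefined = TRUE` when no
#'   pair has any comparable site.
#' @export
nucleotide_diversity <- function(aln) {
  m <- unclass(aln)
  n <- nrow(m)
  stopifnot(n >= 2L)
  ok <- matrix(m %in% VALID_STATES, nrow = n)
  pair_pi <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- ok[i, ] & ok[j, ]
    nc <- sum(comp)
    pair_pi <- c(pair_pi, if (nc == 0L) NA_real_ else
      sum(m[i, comp] != m[j, comp]) / nc)
  }
  if (all(is.na(pair_pi))) {
    return(structure(NaN, undefined = TRUE))
  }
  mean(pair_pi, na.rm = TRUE)
}

#' Segregating sites and the proportion of variability
#'
#' @param aln A `gene_alignment` with at least two rows.
#' @return List with `S` (count of columns holding >= 2 distinct determinate
#'   states) and `PV = S / aligned_length`.
#' @export
segregating_stats <- function(aln) {
  m <- unclass(aln)
  stopifnot(nrow(m) >= 2L)
  S <- sum(apply(m, 2L, function(col) {
    length(unique(col[col %in% VALID_STATES])) >= 2L
  }))
  list(S = as.integer(S), PV = S / ncol(m))
}

#' Sliding-window nucleotide diversity profile
#'
#' Computes pi on successive column slices. Defaults follow the standard
#' plastome screening setup: 600 bp windows advanced in 100 bp steps.
#'
#' @param aln A `gene_alignment`.
#' @param window Window length in alignment columns.
#' @param step Step size in columns.
#' @return A `sliding_window_profile`: data frame with `start` (0-based),
#'   `midpoint` and `pi`, plus `window`/`step` attributes.
#' @export
sliding_window_pi <- function(aln, window = 600L, step = 100L) {
  L <- ncol(aln)
  if (L < window) {
    warning("alignment shorter than window; returning one whole-alignment window")
    window <- L
    step <- L
  }
  starts <- seq(0L, L - window, by = step)
  pis <- vapply(starts, function(s) {
    sub <- unclass(aln)[, (s + 1L):(s + window), drop = FALSE]
    as.numeric(nucleotide_diversity(gene_alignment(sub, attr(aln, "gene_name"))))
  }, 0)
  structure(
    data.frame(start = starts, midpoint = starts + window / 2, pi = pis),
    window = window, step = step,
    class = c("sliding_window_profile", "data.frame"))
}

#' Screen high-variability regions from a window profile
#'
#' Maximal runs of consecutive windows whose pi strictly exceeds the
#' threshold are merged into regions.
#'
#' @param profile A `sliding_window_profile`.
#' @param threshold Pi threshold (default 0.006).
#' @return Data frame with `start`, `end` (0-based half-open, in columns)
#'   and `max_pi` per region; zero rows when nothing qualifies.
#' @export
screen_hotspots <- function(profile, threshold = 0.006) {
  stopifnot(nrow(profile) >= 1L)
  window <- attr(profile, "window")
  hot <- !is.na(profile$pi) & profile$pi > threshold
  out <- data.frame(start = integer(), end = integer(), max_pi = numeric())
  if (!any(hot)) return(out)
  r <- rle(hot)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  for (k in which(r$values)) {
    i <- idx_start[k]:idx_end[k]
    out <- rbind(out, data.frame(
      start = profile$start[i[1L]],
      end = profile$start[i[length(i)]] + window,
      max_pi = max(profile$pi[i])))
  }
  out
}

#' GC content
#'
#' @param x A sequence string, a character vector of sequences, or a
#'   `gene_alignment`. Gaps and Ns are excluded from the denominator.
#' @return Fraction (G+C)/(A+C+G+T); `NaN` flagged `undefined` if the
#'   denominator is zero.
#' @export
gc_content <- function(x) {
  ch <- if (inherits(x, "gene_alignment")) as.vector(unclass(x))
        else str_chars(paste(toupper(x), collapse = ""))
  acgt <- sum(ch %in% VALID_STATES)
  if (acgt == 0L) return(structure(NaN, undefined = TRUE))
  sum(ch %in% c("G", "C")) / acgt
}

#' Per-gene summary statistics table
#'
#' Convenience wrapper producing one row per gene with GC content, aligned
#' length, S, PV and pi.
#'
#' @param alns Named list of `gene_alignment`s.
#' @return Data frame keyed by `gene`.
#' @export
gene_stats_table <- function(alns) {
  rows <- lapply(names(alns), function(g) {
    a <- alns[[g]]
    ss <- segregating_stats(a)
    data.frame(gene = g, gc = as.numeric(gc_content(a)),
               aligned_length = ncol(a), S = ss$S, PV = ss$PV,
               pi = as.numeric(nucleotide_diversity(a)))
  })
  do.call(rbind, rows)
}
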