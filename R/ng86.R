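## Nei-Gojobori (1986) counting estimator of synonymous and nonsynonymous
## substitution rates, with pathway averaging for multi-hit codons and the
## Jukes-Cantor multiple-hit correction.
##
## Site counting: at each codon position the unit site is split between
## synonymous and nonsynonymous in proportion to the synonymous fraction of
## the single-nucleotide changes at that position, computed over the
## alternatives that do not create a stop codon. This keeps
## N_sites + S_sites = 3 per compared codon while excluding stop pathways,
## consistent with the pathway rule below.
##
## Difference counting: for codons differing at d positions, all d! orderings
## of the changes are enumerated; orderings that pass through a stop codon
## are discarded and synonymous/nonsynonymous step counts are averaged over
## the remainder (over all orderings if every one is blocked).

STOP_CODONS <- c("TAA", "TAG", "TGA")

codon_env <- new.env(parent = emptyenv())

## Translate one codon using the standard (= plastid) genetic code.
codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

codon_tables <- function() {
  if (!is.null(codon_env$tab)) return(codon_env$tab)
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES,
                              stringsAsFactors = FALSE)[, 3:1], 1L,
                  paste, collapse = "")
  sense <- setdiff(codons, STOP_CODONS)
  syn_sites <- stats::setNames(numeric(length(sense)), sense)
  for (cd in sense) {
    s <- 0
    for (pos in 1:3) {
      alts <- vapply(setdiff(DNA_BASES, substr(cd, pos, pos)), function(b) {
        x <- cd; substr(x, pos, pos) <- b; x
      }, "")
      alts <- alts[!alts %in% STOP_CODONS]
      if (!length(alts)) next    # cannot happen for sense codons, kept for safety
      s <- s + mean(codon_aa(alts) == codon_aa(cd))
    }
    syn_sites[cd] <- s
  }
  codon_env$tab <- list(sense = sense, syn_sites = syn_sites)
  codon_env$tab
}

## Average (syn, nonsyn) step counts over valid mutational pathways between
## two codons. Returns c(S_diff, N_diff); sums to the number of differing
## positions.
codon_path_diffs <- function(a, b) {
  pos <- which(str_chars(a) != str_chars(b))
  d <- length(pos)
  if (d == 0L) return(c(0, 0))
  perms <- if (d == 1L) list(pos) else {
    idx <- if (d == 2L) list(pos, rev(pos)) else {
      p <- list()
      for (i in 1:3) for (j in setdiff(1:3, i))
        p[[length(p) + 1L]] <- pos[c(i, j, setdiff(1:3, c(i, j)))]
      p
    }
    idx
  }
  acc <- matrix(NA_real_, nrow = length(perms), ncol = 2L)
  valid <- logical(length(perms))
  for (k in seq_along(perms)) {
    cur <- a; sd <- 0; nd <- 0; ok <- TRUE
    for (p in perms[[k]]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (nxt %in% STOP_CODONS) { ok <- FALSE; break }
      if (codon_aa(cur) == codon_aa(nxt)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    valid[k] <- ok
    if (ok) acc[k, ] <- c(sd, nd)
  }
  if (!any(valid)) {
    ## every ordering passes through a stop: fall back to averaging over all
    ## orderings, counting steps to/through stops as nonsynonymous
    for (k in seq_along(perms)) {
      cur <- a; sd <- 0; nd <- 0
      for (p in perms[[k]]) {
        nxt <- cur
        substr(nxt, p, p) <- substr(b, p, p)
        aa_c <- if (cur %in% STOP_CODONS) "*" else codon_aa(cur)
        aa_n <- if (nxt %in% STOP_CODONS) "*" else codon_aa(nxt)
        if (identical(aa_c, aa_n)) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      acc[k, ] <- c(sd, nd)
    }
    valid[] <- TRUE
  }
  colMeans(acc[valid, , drop = FALSE])
}

#' Jukes-Cantor distance from a proportion of differences
#' @param p Proportion of differing sites.
#' @return `-(3/4) log(1 - 4p/3)`; `NA` (saturated) when `p >= 3/4`.
#' @export
jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Pairwise Nei-Gojobori dN/dS
#'
#' Counting-method estimate of synonymous and nonsynonymous substitution
#' rates between two aligned coding sequences under the standard genetic
#' code. Codons containing gaps, Ns or stop codons in either sequence are
#' skipped pairwise.
#'
#' @param a,b Aligned coding nucleotide strings of equal length divisible
#'   by 3.
#' @return List with `N_sites`, `S_sites`, `N_diffs`, `S_diffs`, `pN`, `pS`,
#'   `dN`, `dS`, `omega` (`NA` when `dS` is 0 or saturated) and `saturated`
#'   (logical per rate).
#' @export
ng86_pair <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  stopifnot(nchar(a) == nchar(b), nchar(a) %% 3 == 0)
  tab <- codon_tables()
  nc <- nchar(a) %/% 3
  S_sites <- 0; N_sites <- 0; S_diffs <- 0; N_diffs <- 0; used <- 0L
  for (i in seq_len(nc)) {
    ca <- substr(a, 3 * i - 2, 3 * i)
    cb <- substr(b, 3 * i - 2, 3 * i)
    if (!(ca %in% tab$sense) || !(cb %in% tab$sense)) next
    used <- used + 1L
    s_a <- tab$syn_sites[[ca]]; s_b <- tab$syn_sites[[cb]]
    S_sites <- S_sites + (s_a + s_b) / 2
    N_sites <- N_sites + 3 - (s_a + s_b) / 2
    if (ca != cb) {
      d <- codon_path_diffs(ca, cb)
      S_diffs <- S_diffs + d[1L]
      N_diffs <- N_diffs + d[2L]
    }
  }
  pS <- if (S_sites > 0) S_diffs / S_sites else 0
  pN <- if (N_sites > 0) N_diffs / N_sites else 0
  dS <- jc_correct(pS)
  dN <- jc_correct(pN)
  omega <- if (is.na(dN) || is.na(dS) || dS == 0) NA_real_ else dN / dS
  list(N_sites = N_sites, S_sites = S_sites,
       N_diffs = N_diffs, S_diffs = S_diffs,
       pN = pN, pS = pS, dN = dN, dS = dS, omega = omega,
       codons_compared = used,
       saturated = c(dN = is.na(dN) && pN >= 0.75, dS = is.na(dS) && pS >= 0.75))
}
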