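# Independent oracles: deliberately naive re-implementations used to check
# the package's optimized paths. They share no code with the package
# internals beyond base R and the ape/phangorn containers.

# mean pairwise difference per comparable site, written as the obvious
# double loop over columns
oracle_pi <- function(m) {
  n <- nrow(m)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    diffs <- 0L; comp <- 0L
    for (col in seq_len(ncol(m))) {
      a <- m[i, col]; b <- m[j, col]
      if (a %in% c("A", "C", "G", "T") && b %in% c("A", "C", "G", "T")) {
        comp <- comp + 1L
        if (a != b) diffs <- diffs + 1L
      }
    }
    vals <- c(vals, if (comp) diffs / comp else NA_real_)
  }
  mean(vals, na.rm = TRUE)
}

oracle_S <- function(m) {
  s <- 0L
  for (col in seq_len(ncol(m))) {
    states <- unique(m[, col])
    states <- states[states %in% c("A", "C", "G", "T")]
    if (length(states) >= 2L) s <- s + 1L
  }
  s
}

# --- NG86 enumeration oracle ------------------------------------------------

oracle_codons <- function() {
  b <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(codons, c("TAA", "TAG", "TGA"))
}

oracle_translate <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

# per-codon synonymous site count: at each position, the synonymous
# fraction of the single-nucleotide changes that avoid stop codons
oracle_syn_sites <- function(codon) {
  b <- c("A", "C", "G", "T")
  aa <- oracle_translate(codon)
  total <- 0
  for (pos in 1:3) {
    muts <- c()
    for (alt in setdiff(b, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- alt
      if (!mut %in% c("TAA", "TAG", "TGA")) muts <- c(muts, mut)
    }
    if (length(muts))
      total <- total + sum(oracle_translate(muts) == aa) / length(muts)
  }
  total
}

# pathway-enumerated (syn, nonsyn) differences between two codons,
# excluding orderings that pass through a stop
oracle_path_diffs <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  perms <- if (length(pos) == 1) list(pos) else {
    do.call(c, lapply(seq_along(pos), function(i) {
      rest <- pos[-i]
      if (length(rest) == 1) list(c(pos[i], rest))
      else lapply(seq_along(rest), function(j)
        c(pos[i], rest[j], rest[-j]))
    }))
  }
  paths <- list()
  for (ord in perms) {
    cur <- a; steps <- c(0, 0); ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (nxt %in% c("TAA", "TAG", "TGA")) { ok <- FALSE; break }
      if (oracle_translate(cur) == oracle_translate(nxt))
        steps[1] <- steps[1] + 1 else steps[2] <- steps[2] + 1
      cur <- nxt
    }
    if (ok) paths[[length(paths) + 1]] <- steps
  }
  if (!length(paths)) return(NULL)  # all pathways blocked
  Reduce(`+`, paths) / length(paths)
}

# --- small tree fixtures ----------------------------------------------------

tree_from_newick <- function(txt) ape::read.tree(text = txt)

# named list of alignments simulated from one tree, for concatenation tests
sim_alignment_set <- function(tree, genes, length = 400, seed = 1) {
  alns <- lapply(seq_along(genes), function(i)
    simulate_alignment(tree, length, gc_target = 0.4, subst_rate = 0.1,
                       seed = seed + i))
  names(alns) <- genes
  alns
}
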