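## Plastome structure characterization: coding-sequence extraction, exact
## inverted-repeat detection with quadripartite partitioning, IR junction
## reports, and gene presence/absence across accessions.

splice_feature <- function(record, f) {
  segs <- apply(f$intervals, 1L, function(iv)
    substr(record$sequence, iv[1L] + 1L, iv[2L]))
  joined <- paste(segs, collapse = "")
  if (f$strand == "-") revcomp(joined) else joined
}

#' Extract protein-coding gene sequences
#'
#' Minus-strand features are reverse-complemented and multi-interval joins
#' spliced in annotation order. A gene annotated twice with identical
#' sequence (the inverted-repeat duplicates) is emitted once; differing
#' copies are kept with `_1`/`_2` suffixes and a warning. Internal stop
#' codons trigger a warning but the sequence is still returned.
#'
#' @param record A `plastome_record`.
#' @return Named character vector: gene name to coding nucleotide sequence.
#' @export
extract_pcgs <- function(record) {
  cds <- Filter(function(f) f$kind == "CDS", record$features)
  if (!length(cds)) return(stats::setNames(character(0), character(0)))
  seqs <- vapply(cds, splice_feature, "", record = record)
  names(seqs) <- vapply(cds, `[[`, "", "gene")
  out <- character(0)
  for (g in unique(names(seqs))) {
    copies <- unique(seqs[names(seqs) == g])
    if (length(copies) == 1L) {
      out[g] <- copies
    } else {
      warning("gene '", g, "' has ", length(copies),
              " non-identical copies; kept with suffixes")
      for (i in seq_along(copies)) out[paste0(g, "_", i)] <- copies[i]
    }
  }
  for (g in names(out)) {
    s <- out[[g]]
    if (nchar(s) %% 3 == 0 && nchar(s) >= 6) {
      inner <- substring(s, seq(1L, nchar(s) - 5L, 3L), seq(3L, nchar(s) - 3L, 3L))
      if (any(inner %in% STOP_CODONS))
        warning("gene '", g, "' contains an internal stop codon")
    }
  }
  out
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## Extend an exact inverted match seq[a1..b1] == revcomp(seq[a2..b2])
## outward/inward as far as possible (1-based inclusive coordinates);
## block-wise string comparison keeps this fast on long repeats.
extend_ir <- function(s, L, a1, b1, a2, b2) {
  block_ok <- function(x1, y1, x2, y2) {
    substr(s, x1, y1) == revcomp(substr(s, x2, y2))
  }
  w <- 512L
  while (w >= 1L) {   # grow left of copy1 with right of copy2
    while (a1 - w >= 1L && b2 + w <= L &&
           block_ok(a1 - w, a1 - 1L, b2 + 1L, b2 + w)) {
      a1 <- a1 - w; b2 <- b2 + w
    }
    w <- w %/% 2L
  }
  w <- 512L
  while (w >= 1L) {   # grow right of copy1 with left of copy2
    while (b1 + w < a2 - w + 1L &&
           block_ok(b1 + 1L, b1 + w, a2 - w, a2 - 1L)) {
      b1 <- b1 + w; a2 <- a2 - w
    }
    w <- w %/% 2L
  }
  c(a1, b1, a2, b2)
}

#' Detect the quadripartite plastome structure
#'
#' Finds the longest pair of exact reverse-complement repeats of at least
#' `min_ir_len` by k-mer seeding and block extension; the shorter enclosed
#' single-copy segment is labelled SSC and the longer LSC. Intervals are
#' 0-based half-open on the record's linear coordinates (the IR is assumed
#' not to span the sequence origin, the convention plastome assemblies
#' follow by starting in the LSC).
#'
#' @param record A `plastome_record` (>= 10 kb).
#' @param min_ir_len Minimum repeat length to call an IR (default 1000 bp).
#' @param k Seed k-mer length.
#' @return A `quadripartite_structure`: list with `found`, and when found
#'   `lsc`, `irb`, `ssc`, `ira` intervals `c(start, end)` plus `ir_length`.
#' @export
detect_quadripartite <- function(record, min_ir_len = 1000L, k = 31L) {
  s <- record$sequence
  L <- record$length
  if (L < 10000L) stop("record shorter than 10 kb")
  rc <- revcomp(s)
  stride <- max(1L, min_ir_len %/% 2L)
  best <- NULL
  claimed <- matrix(numeric(0), ncol = 2L)
  for (p in seq(1L, L - k + 1L, by = stride)) {
    if (nrow(claimed) &&
        any(p >= claimed[, 1L] & p + k - 1L <= claimed[, 2L])) next
    kmer <- substr(s, p, p + k - 1L)
    if (grepl("N", kmer, fixed = TRUE)) next
    hits <- gregexpr(kmer, rc, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) next
    for (q in as.integer(hits)) {
      s2 <- L - (q + k - 1L) + 1L      # start of the partner copy in s
      a1 <- p; b1 <- p + k - 1L; a2 <- s2; b2 <- s2 + k - 1L
      if (a2 < a1) { tmp <- c(a1, b1); a1 <- a2; b1 <- b2; a2 <- tmp[1L]; b2 <- tmp[2L] }
      if (b1 >= a2) next               # overlapping/self match
      ext <- extend_ir(s, L, a1, b1, a2, b2)
      if (ext[2L] >= ext[3L]) next
      len <- ext[2L] - ext[1L] + 1L
      claimed <- rbind(claimed, c(ext[1L], ext[2L]), c(ext[3L], ext[4L]))
      if (len >= min_ir_len && (is.null(best) || len > best$len))
        best <- list(len = len, c1 = ext[1:2], c2 = ext[3:4])
    }
  }
  if (is.null(best))
    return(structure(list(found = FALSE, min_ir_len = min_ir_len),
                     class = "quadripartite_structure"))
  ## 0-based half-open intervals of the two copies
  c1 <- c(best$c1[1L] - 1L, best$c1[2L])
  c2 <- c(best$c2[1L] - 1L, best$c2[2L])
  inner <- c(c1[2L], c2[1L])                      # between the copies
  outer_len <- (L - c2[2L]) + c1[1L]              # wraps the origin
  inner_len <- inner[2L] - inner[1L]
  if (inner_len <= outer_len) {
    ssc <- inner
    lsc <- c(c2[2L] %% L, c1[1L])                 # circular interval
    irb <- c1; ira <- c2
  } else {
    ssc <- c(c2[2L] %% L, c1[1L])
    lsc <- inner
    irb <- c2; ira <- c1
  }
  structure(list(found = TRUE, lsc = lsc, irb = irb, ssc = ssc, ira = ira,
                 ir_length = best$len, min_ir_len = min_ir_len),
            class = "quadripartite_structure")
}

#' @export
print.quadripartite_structure <- function(x, ...) {
  if (!x$found) {
    cat("<quadripartite_structure> no IR >= ", x$min_ir_len, " bp detected\n",
        sep = "")
  } else {
    cat("<quadripartite_structure> IR length ", x$ir_length, " bp\n",
        "  LSC [", x$lsc[1L], ",", x$lsc[2L], ")  IRb [", x$irb[1L], ",",
        x$irb[2L], ")  SSC [", x$ssc[1L], ",", x$ssc[2L], ")  IRa [",
        x$ira[1L], ",", x$ira[2L], ")\n", sep = "")
  }
  invisible(x)
}

#' Report IR junction positions relative to nearby genes
#'
#' For each of the four junctions (JLB: LSC/IRb, JSB: IRb/SSC, JSA:
#' SSC/IRa, JLA: IRa/LSC) the nearest annotated feature edge is reported
#' with its signed offset: negative when the feature lies inside the IR,
#' and the overlap length (with `spans_junction = TRUE`) when the junction
#' falls inside the feature.
#'
#' @param structures List of `quadripartite_structure`s.
#' @param records List of matching `plastome_record`s.
#' @return Data frame `(taxon, junction, gene, offset_bp, spans_junction)`;
#'   records without a detected IR are skipped with a message.
#' @export
junction_report <- function(structures, records) {
  stopifnot(length(structures) == length(records))
  rows <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]; st <- structures[[i]]
    if (!isTRUE(st$found)) {
      message("record '", rec$id, "' has no detected IR; skipped")
      next
    }
    junctions <- c(JLB = st$irb[1L], JSB = st$irb[2L],
                   JSA = st$ira[1L], JLA = st$ira[2L] %% rec$length)
    in_ir <- function(pos) {
      (pos >= st$irb[1L] && pos < st$irb[2L]) ||
        (pos >= st$ira[1L] && pos < st$ira[2L])
    }
    for (jn in names(junctions)) {
      j <- junctions[[jn]]
      best <- NULL
      for (f in rec$features) {
        for (r in seq_len(nrow(f$intervals))) {
          iv <- f$intervals[r, ]
          if (iv[1L] < j && j < iv[2L]) {
            ov <- min(iv[2L] - j, j - iv[1L])
            cand <- list(gene = f$gene, offset = ov, spans = TRUE, d = 0)
          } else {
            d <- min(abs(iv[1L] - j), abs(iv[2L] - j))
            mid <- (iv[1L] + iv[2L]) / 2
            cand <- list(gene = f$gene,
                         offset = if (in_ir(mid)) -d else d,
                         spans = FALSE, d = d)
          }
          if (is.null(best) || cand$d < best$d) best <- cand
        }
      }
      if (!is.null(best))
        rows[[length(rows) + 1L]] <- data.frame(
          taxon = rec$id, junction = jn, gene = best$gene,
          offset_bp = best$offset, spans_junction = best$spans)
    }
  }
  if (!length(rows))
    return(data.frame(taxon = character(), junction = character(),
                      gene = character(), offset_bp = integer(),
                      spans_junction = logical()))
  do.call(rbind, rows)
}

#' Gene presence/absence across plastome records
#'
#' @param records List of >= 2 `plastome_record`s.
#' @return List with `matrix` (gene x taxon logical, over the union of
#'   gene names; IR duplicates count once) and `loss_events` (data frame
#'   `gene`, `taxon` of absences among genes present in at least one
#'   taxon).
#' @export
presence_absence <- function(records) {
  stopifnot(length(records) >= 2L)
  taxa <- vapply(records, `[[`, "", "id")
  gene_sets <- lapply(records, function(r)
    unique(vapply(r$features, `[[`, "", "gene")))
  genes <- sort(unique(unlist(gene_sets)))
  m <- vapply(gene_sets, function(gs) genes %in% gs,
              logical(length(genes)))
  dimnames(m) <- list(genes, taxa)
  idx <- which(!m, arr.ind = TRUE)
  loss <- data.frame(gene = genes[idx[, 1L]], taxon = taxa[idx[, 2L]])
  loss <- loss[order(loss$gene, loss$taxon), ]
  rownames(loss) <- NULL
  list(matrix = m, loss_events = loss)
}
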