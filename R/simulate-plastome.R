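## Synthetic plastomes with planted ground truth: a quadripartite layout
## (LSC + IRb + SSC + IRa, the IRa being the exact reverse complement of
## IRb), planted protein-coding genes on both strands, planted SSR motifs
## at recorded positions, and an optional single-gene deletion. The random
## backbone is scrubbed of incidental SSRs so that the planted motifs are
## exactly the reportable set, and every planted object is emitted in a
## machine-readable truth table.

## One random stop-free coding sequence of `n_codons` codons (ATG ... stop).
random_cds <- function(n_codons, gc) {
  tab <- codon_tables()
  w <- vapply(tab$sense, function(cd) {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    prod(p[str_chars(cd)])
  }, 0)
  body <- sample(tab$sense, n_codons - 2L, replace = TRUE, prob = w)
  paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1L))
}

## Remove incidental SSRs from a plain backbone string (no genes inside).
scrub_ssrs <- function(s, min_units = DEFAULT_SSR_MINIMA) {
  for (iter in 1:50) {
    hits <- find_ssrs(s, min_units)
    if (!nrow(hits)) return(s)
    h <- hits[1L, ]
    pos <- h$start + (h$end - h$start) %/% 2L + 1L
    cur <- substr(s, pos, pos)
    substr(s, pos, pos) <- setdiff(DNA_BASES, cur)[1L]
  }
  stop("failed to scrub incidental SSRs from backbone")
}

default_gene_names <- function(n) sprintf("pg%02d", seq_len(n))

#' Default synthetic-plastome configuration
#'
#' The defaults emulate a down-scaled plastid genome: a quadripartite
#' layout with an exact IR, ~30 coding genes (two duplicated in the IR),
#' plastome-like GC around 0.39, and a handful of planted SSRs.
#'
#' @param seed Integer seed.
#' @param ... Overrides for any field (`id`, `n_genes`, `n_ir_genes`,
#'   `gene_length_range`, `gc`, `ir_length`, `lsc_length`, `ssc_length`,
#'   `ssr_plan` (data frame `motif`, `unit_count`, `insert_position`;
#'   positions are LSC-local, 0-based), `delete_gene`, `gene_names`).
#' @return A named list configuration.
#' @export
plastome_config <- function(seed = 1L, ...) {
  cfg <- list(
    id = "synplastome",
    seed = seed,
    n_genes = 30L,
    n_ir_genes = 2L,
    gene_length_range = c(300L, 900L),
    gc = 0.39,
    ir_length = 5000L,
    lsc_length = 24000L,
    ssc_length = 8000L,
    ssr_plan = data.frame(motif = c("A", "AT", "ATAG"),
                          unit_count = c(12L, 8L, 4L),
                          insert_position = c(500L, 1500L, 2500L)),
    delete_gene = NULL,
    gene_names = NULL)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Simulate an annotated plastome with planted ground truth
#'
#' @param config A list from [plastome_config()].
#' @return A `plastome_record` with attribute `truth`: list holding
#'   `regions` (LSC/IRb/SSC/IRa intervals, 0-based half-open), `genes`
#'   (planted positions/strands), `ssrs` (absolute coordinates) and
#'   `deleted_gene`.
#' @export
simulate_plastome <- function(config = plastome_config()) {
  cfg <- config
  if (cfg$ir_length < 1000L) stop("ir_length must be >= 1000")
  total <- cfg$lsc_length + cfg$ssc_length + 2L * cfg$ir_length
  if (total <= 2L * cfg$ir_length + 2000L)
    stop("total length must exceed 2*ir_length + 2000")
  ssr_plan <- cfg$ssr_plan
  if (!is.null(ssr_plan) && nrow(ssr_plan)) {
    bad <- vapply(ssr_plan$motif, is_periodic_motif, TRUE) |
      nchar(ssr_plan$motif) > 6L
    if (any(bad)) stop("SSR motifs must be non-periodic units of length 1-6")
  }
  names_all <- cfg$gene_names %||% default_gene_names(cfg$n_genes)
  stopifnot(length(names_all) == cfg$n_genes)
  if (!is.null(cfg$delete_gene) && !cfg$delete_gene %in% names_all)
    stop("delete_gene '", cfg$delete_gene, "' is not among the gene names")

  with_seed(derive_seed(cfg$seed, "plastome", cfg$id), {
    n_ir <- min(cfg$n_ir_genes, cfg$n_genes)
    n_sc <- cfg$n_genes - n_ir
    n_lsc <- ceiling(n_sc * 0.75)
    n_ssc <- n_sc - n_lsc

    gene_seq <- stats::setNames(vapply(seq_len(cfg$n_genes), function(i) {
      n_cod <- sample(seq(cfg$gene_length_range[1L] %/% 3L,
                          cfg$gene_length_range[2L] %/% 3L), 1L)
      for (try in 1:20) {
        s <- random_cds(n_cod, cfg$gc)
        if (!nrow(find_ssrs(s))) return(s)
      }
      stop("could not generate an SSR-free gene sequence")
    }, ""), names_all)

    ## Build one segment: genes separated by scrubbed random spacers,
    ## padded to exactly `seg_len`. Returns list(seq, placements).
    build_segment <- function(genes, seg_len, region) {
      body_len <- sum(nchar(gene_seq[genes]))
      n_gaps <- length(genes) + 1L
      spare <- seg_len - body_len
      if (spare < n_gaps * 20L)
        stop("segment ", region, " too short for its genes")
      cuts <- if (n_gaps > 1L)
        sort(sample.int(spare - n_gaps * 20L, n_gaps - 1L, replace = FALSE))
      else integer(0)
      gaps <- diff(c(0L, cuts, spare - n_gaps * 20L)) + 20L
      pieces <- character(0); placements <- list(); pos <- 0L
      for (i in seq_along(genes)) {
        sp <- scrub_ssrs(random_dna(gaps[i], cfg$gc))
        pieces <- c(pieces, sp); pos <- pos + nchar(sp)
        g <- gene_seq[[genes[i]]]
        strand <- sample(c("+", "-"), 1L)
        placed <- if (strand == "-") revcomp(g) else g
        placements[[i]] <- data.frame(gene = genes[i], start = pos,
                                      end = pos + nchar(g), strand = strand,
                                      region = region)
        pieces <- c(pieces, placed); pos <- pos + nchar(g)
      }
      sp <- scrub_ssrs(random_dna(gaps[n_gaps], cfg$gc))
      pieces <- c(pieces, sp)
      list(seq = paste(pieces, collapse = ""),
           placements = if (length(placements)) do.call(rbind, placements)
                        else NULL)
    }

    lsc_genes <- names_all[seq_len(n_lsc)]
    ssc_genes <- if (n_ssc) names_all[n_lsc + seq_len(n_ssc)] else character(0)
    ir_genes <- if (n_ir) names_all[n_sc + seq_len(n_ir)] else character(0)
    ## genes that cannot fit in the IR move to the LSC
    while (length(ir_genes) &&
           sum(nchar(gene_seq[ir_genes])) +
             20L * (length(ir_genes) + 1L) > cfg$ir_length) {
      lsc_genes <- c(lsc_genes, ir_genes[length(ir_genes)])
      ir_genes <- ir_genes[-length(ir_genes)]
    }

    deleted <- cfg$delete_gene

    ## the LSC opens with a gene-free prefix reserved for the SSR plan
    planted_ssr <- NULL
    prefix <- ""
    if (!is.null(ssr_plan) && nrow(ssr_plan)) {
      ends <- ssr_plan$insert_position +
        ssr_plan$unit_count * nchar(ssr_plan$motif)
      o <- order(ssr_plan$insert_position)
      sp <- ssr_plan[o, ]; ends <- ends[o]
      if (any(sp$insert_position[-1L] < ends[-length(ends)] + nchar(sp$motif[-1L])))
        stop("planted SSR overlaps another planted SSR")
      prefix_len <- max(ends) + 20L
      if (prefix_len > cfg$lsc_length %/% 2L)
        stop("SSR plan does not fit the first half of the LSC")
      prefix <- scrub_ssrs(random_dna(prefix_len, cfg$gc))
      for (r in seq_len(nrow(sp))) {
        motif <- toupper(sp$motif[r])
        units <- sp$unit_count[r]
        s0 <- sp$insert_position[r]                 # 0-based LSC-local
        run <- strrep(motif, units)
        e0 <- s0 + nchar(run)
        substr(prefix, s0 + 1L, e0) <- run
        ## make sure the run does not extend into the flanks
        first <- substr(motif, 1L, 1L)
        last <- substr(motif, nchar(motif), nchar(motif))
        if (s0 >= 1L && substr(prefix, s0, s0) == last)
          substr(prefix, s0, s0) <- setdiff(DNA_BASES, c(last, first))[1L]
        if (substr(prefix, e0 + 1L, e0 + 1L) == first)
          substr(prefix, e0 + 1L, e0 + 1L) <- setdiff(DNA_BASES, c(first, last))[1L]
        planted_ssr <- rbind(planted_ssr, data.frame(
          motif = canonical_rotation(motif), unit_count = units,
          start = s0, end = e0))
      }
    }

    lsc_build <- build_segment(setdiff(lsc_genes, deleted),
                               cfg$lsc_length - nchar(prefix), "LSC")
    if (!is.null(lsc_build$placements)) {
      lsc_build$placements$start <- lsc_build$placements$start + nchar(prefix)
      lsc_build$placements$end <- lsc_build$placements$end + nchar(prefix)
    }
    lsc_build$seq <- paste0(prefix, lsc_build$seq)
    ssc_build <- build_segment(setdiff(ssc_genes, deleted), cfg$ssc_length, "SSC")
    irb_build <- build_segment(setdiff(ir_genes, deleted), cfg$ir_length, "IRb")

    lsc <- lsc_build$seq

    irb <- irb_build$seq
    ira <- revcomp(irb)
    genome <- paste0(lsc, irb, ssc_build$seq, ira)

    off_irb0 <- nchar(lsc)
    off_ira0 <- nchar(lsc) + nchar(irb) + nchar(ssc_build$seq)

    ## pin the SSC flanks so a chance complement at the junctions cannot
    ## extend the exact repeat beyond the planted boundaries
    ssc_first <- off_irb0 + nchar(irb) + 1L
    ssc_last <- off_ira0
    if (substr(genome, ssc_first, ssc_first) ==
        COMPLEMENT[[substr(genome, ssc_last, ssc_last)]]) {
      avoid <- c(COMPLEMENT[[substr(genome, ssc_last, ssc_last)]],
                 substr(genome, ssc_first + 1L, ssc_first + 1L))
      substr(genome, ssc_first, ssc_first) <- setdiff(DNA_BASES, avoid)[1L]
    }

    ## final pass: mutate away any unplanned SSR arising at segment or
    ## insertion boundaries (kept symmetric inside the IR copies)
    total_len <- nchar(genome)
    ssc_pl <- ssc_build$placements
    if (!is.null(ssc_pl)) {
      ssc_pl$start <- ssc_pl$start + off_irb0 + nchar(irb)
      ssc_pl$end <- ssc_pl$end + off_irb0 + nchar(irb)
    }
    irb_pl <- irb_build$placements
    ira_pl <- NULL
    if (!is.null(irb_pl)) {
      ira_pl <- irb_pl
      ira_pl$start <- off_ira0 + (cfg$ir_length - irb_pl$end)
      ira_pl$end <- off_ira0 + (cfg$ir_length - irb_pl$start)
      irb_pl$start <- irb_pl$start + off_irb0
      irb_pl$end <- irb_pl$end + off_irb0
    }
    gene_iv <- rbind(lsc_build$placements, ssc_pl, irb_pl, ira_pl)
    for (pass in 1:50) {
      hits <- find_ssrs(genome)
      planted_ok <- if (is.null(planted_ssr)) rep(FALSE, nrow(hits)) else
        paste(hits$start, hits$end) %in% paste(planted_ssr$start, planted_ssr$end)
      extra <- hits[!planted_ok, , drop = FALSE]
      if (!nrow(extra)) break
      h <- extra[1L, ]
      run_pos <- (h$start + 1L):h$end
      in_gene <- if (is.null(gene_iv)) rep(FALSE, length(run_pos)) else
        vapply(run_pos, function(p)
          any(p > gene_iv$start & p <= gene_iv$end), TRUE)
      cand <- run_pos[!in_gene]
      if (!length(cand)) stop("unplanned SSR inside a gene; cannot scrub")
      pos <- cand[(length(cand) + 1L) %/% 2L]
      cur <- substr(genome, pos, pos)
      substr(genome, pos, pos) <- setdiff(DNA_BASES, cur)[1L]
      if (pos > off_irb0 && pos <= off_irb0 + nchar(irb)) {
        mirror <- off_ira0 + (off_irb0 + nchar(irb) - pos) + 1L
        substr(genome, mirror, mirror) <-
          COMPLEMENT[[substr(genome, pos, pos)]]
      } else if (pos > off_ira0) {
        mirror <- off_irb0 + (total_len - pos) + 1L
        substr(genome, mirror, mirror) <-
          COMPLEMENT[[substr(genome, pos, pos)]]
      }
    }

    off_irb <- nchar(lsc)
    off_ssc <- off_irb + nchar(irb)
    off_ira <- off_ssc + nchar(ssc_build$seq)
    regions <- data.frame(
      region = c("LSC", "IRb", "SSC", "IRa"),
      start = c(0L, off_irb, off_ssc, off_ira),
      end = c(off_irb, off_ssc, off_ira, nchar(genome)))

    shift <- function(df, off) { df$start <- df$start + off; df$end <- df$end + off; df }
    placements <- rbind(
      lsc_build$placements,
      if (!is.null(irb_build$placements)) shift(irb_build$placements, off_irb),
      if (!is.null(ssc_build$placements)) shift(ssc_build$placements, off_ssc))

    features <- lapply(seq_len(nrow(placements)), function(i) {
      p <- placements[i, ]
      list(gene = p$gene, kind = "CDS", strand = p$strand,
           intervals = matrix(c(p$start, p$end), 1L,
                              dimnames = list(NULL, c("start", "end"))))
    })
    ## IR genes appear again, mirrored, in IRa
    if (!is.null(irb_build$placements)) {
      pl <- irb_build$placements
      for (i in seq_len(nrow(pl))) {
        s_local <- cfg$ir_length - pl$end[i]
        e_local <- cfg$ir_length - pl$start[i]
        features[[length(features) + 1L]] <- list(
          gene = pl$gene[i], kind = "CDS",
          strand = if (pl$strand[i] == "+") "-" else "+",
          intervals = matrix(c(off_ira + s_local, off_ira + e_local), 1L,
                             dimnames = list(NULL, c("start", "end"))))
      }
    }

    rec <- plastome_record(cfg$id, genome, features, circular = TRUE)
    attr(rec, "truth") <- list(
      regions = regions,
      genes = placements,
      ssrs = planted_ssr,
      deleted_gene = deleted %||% NA_character_)
    rec
  })
}

#' Write a plastome's planted ground truth as TSV files
#'
#' @param record A simulated `plastome_record` carrying a `truth`
#'   attribute.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_plastome_truth <- function(record, dir) {
  truth <- attr(record, "truth")
  if (is.null(truth)) stop("record carries no truth attribute")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(truth$regions, file.path(dir, "truth_regions.tsv"))
  write_tsv(truth$genes, file.path(dir, "truth_genes.tsv"))
  if (!is.null(truth$ssrs))
    write_tsv(truth$ssrs, file.path(dir, "truth_ssrs.tsv"))
  write_tsv(data.frame(deleted_gene = truth$deleted_gene),
            file.path(dir, "truth_deleted.tsv"))
  invisible(dir)
}
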