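## Minimal GenBank flat-file reader/writer for annotated plastomes.
## Coordinates are 1-based inclusive in the file and 0-based half-open in
## the PlastomeRecord; origin-spanning features on circular records arrive
## naturally as two-interval joins. Only CDS/tRNA/rRNA features are kept.

FEATURE_KINDS <- c("CDS", "tRNA", "rRNA")

#' Construct a plastome record
#'
#' @param id Record identifier.
#' @param sequence Upper-case DNA string over A/C/G/T/N.
#' @param features List of features, each a list with `gene` (name), `kind`
#'   (`CDS`/`tRNA`/`rRNA`), `strand` (`+`/`-`) and `intervals` (matrix with
#'   columns `start`,`end`, 0-based half-open, in annotation order).
#' @param circular Logical; plastomes are circular.
#' @return A `plastome_record`.
#' @export
plastome_record <- function(id, sequence, features = list(), circular = TRUE) {
  sequence <- toupper(sequence)
  bad <- setdiff(unique(str_chars(sequence)), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("ambiguity codes other than N are not supported: ",
         paste(bad, collapse = ", "))
  L <- nchar(sequence)
  for (f in features) {
    if (!nzchar(f$gene)) stop("feature with empty gene name")
    iv <- f$intervals
    if (any(iv[, 1L] < 0L) || any(iv[, 2L] > L) || any(iv[, 1L] >= iv[, 2L]))
      stop("feature '", f$gene, "' has an interval outside [0, ", L, ")")
  }
  structure(list(id = id, sequence = sequence, length = L,
                 circular = circular, features = features),
            class = "plastome_record")
}

#' @export
print.plastome_record <- function(x, ...) {
  cat("<plastome_record> ", x$id, ": ", x$length, " bp, ",
      length(x$features), " features",
      if (x$circular) " (circular)", "\n", sep = "")
  invisible(x)
}

parse_location <- function(loc, feature_name) {
  strand <- "+"
  loc <- gsub("[<>[:space:]]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  iv <- t(vapply(parts, function(p) {
    m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1L]]
    if (length(m) != 3L) {
      m1 <- regmatches(p, regexec("^(\\d+)$", p))[[1L]]
      if (length(m1) == 2L) return(c(as.integer(m1[2L]) - 1L, as.integer(m1[2L])))
      stop("cannot parse location of feature '", feature_name, "': ", p)
    }
    c(as.integer(m[2L]) - 1L, as.integer(m[3L]))
  }, integer(2L)))
  dimnames(iv) <- list(NULL, c("start", "end"))
  list(strand = strand, intervals = iv)
}

#' Read a GenBank flat file into a plastome record
#'
#' @param x Path to a GenBank flat file, or its text as a character vector
#'   of lines.
#' @return A `plastome_record`. CDS features whose joined length is not a
#'   multiple of 3 carry `non_triplet = TRUE`.
#' @export
read_plastome <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("no LOCUS line")
  toks <- strsplit(trimws(locus[1L]), "[[:space:]]+")[[1L]]
  id <- toks[2L]
  circular <- any(grepl("circular", locus[1L]))
  feat_start <- grep("^FEATURES", lines)
  ori_start <- grep("^ORIGIN", lines)
  if (!length(ori_start)) stop("record has no sequence (missing ORIGIN)")
  end_rec <- grep("^//", lines)
  end_rec <- if (length(end_rec)) end_rec[1L] else length(lines) + 1L
  seq_lines <- lines[(ori_start[1L] + 1L):(end_rec - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  features <- list()
  if (length(feat_start)) {
    i <- feat_start[1L] + 1L
    while (i < ori_start[1L]) {
      line <- lines[i]
      key <- trimws(substr(line, 1L, 20L))
      if (nzchar(key) && key %in% FEATURE_KINDS) {
        loc <- trimws(substr(line, 21L, nchar(line)))
        j <- i + 1L
        while (j < ori_start[1L] &&
               !nzchar(trimws(substr(lines[j], 1L, 20L))) &&
               !grepl("^\\s*/", lines[j])) {
          loc <- paste0(loc, trimws(lines[j]))
          j <- j + 1L
        }
        gene <- NA_character_
        while (j < ori_start[1L] && !nzchar(trimws(substr(lines[j], 1L, 20L)))) {
          q <- trimws(lines[j])
          m <- regmatches(q, regexec("^/gene=\"([^\"]+)\"", q))[[1L]]
          if (length(m) == 2L) gene <- m[2L]
          j <- j + 1L
        }
        pl <- parse_location(loc, gene %||% key)
        if (is.na(gene)) gene <- paste0(key, "_", length(features) + 1L)
        f <- list(gene = gene, kind = key, strand = pl$strand,
                  intervals = pl$intervals)
        if (key == "CDS" && sum(pl$intervals[, 2L] - pl$intervals[, 1L]) %% 3 != 0)
          f$non_triplet <- TRUE
        features[[length(features) + 1L]] <- f
        i <- j
      } else i <- i + 1L
    }
  }
  rec <- plastome_record(id, sequence, features, circular = circular)
  rec
}

format_location <- function(f) {
  parts <- apply(f$intervals, 1L, function(iv)
    paste0(iv[1L] + 1L, "..", iv[2L]))
  loc <- if (length(parts) > 1L)
    paste0("join(", paste(parts, collapse = ","), ")") else parts
  if (f$strand == "-") loc <- paste0("complement(", loc, ")")
  loc
}

#' Write a plastome record as a GenBank flat file
#'
#' @param record A `plastome_record`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genbank <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %7d bp    DNA     %s PLN 01-JAN-2026",
                     record$id, record$length,
                     if (record$circular) "circular" else "linear  "), con)
  writeLines(sprintf("DEFINITION  Synthetic plastome record %s.", record$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", record$length), con)
  for (f in record$features) {
    writeLines(sprintf("     %-15s %s", f$kind, format_location(f)), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$gene), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(record$sequence)
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(groups, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
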