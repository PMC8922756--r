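test_that("GenBank round-trip is the identity on synthetic records", {
  rec <- simulate_plastome(plastome_config(
    seed = 5, n_genes = 10, ir_length = 2000,
    lsc_length = 10000, ssc_length = 5000))
  path <- tempfile(fileext = ".gb")
  write_genbank(rec, path)
  rec2 <- read_plastome(path)
  expect_identical(rec2$sequence, rec$sequence)
  expect_identical(rec2$length, rec$length)
  expect_true(rec2$circular)
  expect_equal(length(rec2$features), length(rec$features))
  for (i in seq_along(rec$features)) {
    expect_identical(rec2$features[[i]]$gene, rec$features[[i]]$gene)
    expect_identical(rec2$features[[i]]$strand, rec$features[[i]]$strand)
    expect_equal(unname(rec2$features[[i]]$intervals),
                 unname(rec$features[[i]]$intervals))
  }
})

test_that("GenBank 1-based joins map to 0-based half-open intervals", {
  gb <- c(
    "LOCUS       test                 600 bp    DNA     circular PLN 01-JAN-2026",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(100..250,400..500)",
    "                     /gene=\"demo\"",
    "     CDS             complement(join(550..600,1..30))",
    "                     /gene=\"wrap\"",
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    "//")
  ## build a 600 bp record: 10 bases per group, 60 per line
  seq60 <- strrep("acgtacgtac", 6)
  lines <- vapply(0:9, function(i)
    sprintf("%9d %s", i * 60 + 1,
            paste(substring(seq60, seq(1, 51, 10), seq(10, 60, 10)),
                  collapse = " ")), "")
  gb <- c(gb[1:6], "ORIGIN", lines, "//")
  rec <- read_plastome(gb)
  expect_equal(rec$length, 600L)
  f <- rec$features[[1]]
  expect_equal(unname(f$intervals), matrix(c(99L, 399L, 250L, 500L), 2L))
  ## origin-spanning feature arrives as two intervals with length preserved
  w <- rec$features[[2]]
  expect_identical(w$strand, "-")
  expect_equal(nrow(w$intervals), 2L)
  expect_equal(sum(w$intervals[, 2] - w$intervals[, 1]), 81L)
})

test_that("parse errors name the offending structure", {
  expect_error(read_plastome(c("LOCUS  x 100 bp", "FEATURES", "no origin")),
               "ORIGIN")
  gb <- c("LOCUS       t                 10 bp    DNA     linear PLN",
          "FEATURES             Location/Qualifiers",
          "     CDS             5..50",
          "                     /gene=\"beyond\"",
          "ORIGIN", "        1 acgtacgtac", "//")
  expect_error(read_plastome(gb), "beyond")
  gb2 <- c("LOCUS       t                 4 bp    DNA     linear PLN",
           "ORIGIN", "        1 acrt", "//")
  expect_error(read_plastome(gb2), "ambiguity")
})

test_that("coding sequences come back spliced, stranded, and deduplicated", {
  cds <- "ATGAAATAA"
  genome <- paste0("GGGG", revcomp(cds), "GGGG")
  rec <- plastome_record("m", genome, list(
    list(gene = "minus", kind = "CDS", strand = "-",
         intervals = matrix(c(4L, 13L), 1))))
  expect_identical(unname(extract_pcgs(rec)["minus"]), cds)
  ## identical IR copies collapse to one entry
  rec2 <- plastome_record("d", paste0("AA", cds, "TT", cds, "CC"), list(
    list(gene = "dup", kind = "CDS", strand = "+",
         intervals = matrix(c(2L, 11L), 1)),
    list(gene = "dup", kind = "CDS", strand = "+",
         intervals = matrix(c(13L, 22L), 1))))
  expect_identical(names(extract_pcgs(rec2)), "dup")
  ## internal stop warns but still returns
  rec3 <- plastome_record("s", paste0("ATGTAAAAATAA"), list(
    list(gene = "stopin", kind = "CDS", strand = "+",
         intervals = matrix(c(0L, 12L), 1))))
  expect_warning(out <- extract_pcgs(rec3), "stop")
  expect_identical(unname(out["stopin"]), "ATGTAAAAATAA")
})

test_that("planted inverted repeats are recovered exactly across sizes", {
  for (ir in c(1000L, 5000L, 25000L)) {
    cfg <- plastome_config(seed = ir, ir_length = ir,
                           lsc_length = max(12000L, ir), ssc_length = 6000L,
                           n_genes = 12L)
    rec <- simulate_plastome(cfg)
    st <- detect_quadripartite(rec)
    tr <- attr(rec, "truth")$regions
    expect_true(st$found)
    expect_equal(st$irb, c(tr$start[2], tr$end[2]))
    expect_equal(st$ira, c(tr$start[4], tr$end[4]))
    expect_equal(st$ssc, c(tr$start[3], tr$end[3]))
    expect_equal(st$ir_length, ir)
  }
})

test_that("a repeat-free genome yields a no-IR result, not an error", {
  set.seed(42)
  seq <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
               collapse = "")
  rec <- plastome_record("norep", seq)
  st <- detect_quadripartite(rec)
  expect_false(st$found)
})

test_that("an IR contraction is reported at the shorter copy's length", {
  cfg <- plastome_config(seed = 8, ir_length = 3000L, lsc_length = 12000L,
                         ssc_length = 6000L, n_genes = 10L, n_ir_genes = 0L)
  rec <- simulate_plastome(cfg)
  tr <- attr(rec, "truth")$regions
  ## shorten IRb by 200 bp: overwrite its first 200 bases with fresh sequence
  s <- rec$sequence
  repl <- chartr("ACGT", "GTAC", substr(s, tr$start[2] + 1, tr$start[2] + 200))
  substr(s, tr$start[2] + 1, tr$start[2] + 200) <- repl
  rec2 <- plastome_record("contracted", s)
  st <- detect_quadripartite(rec2)
  expect_true(st$found)
  expect_equal(st$ir_length, 2800L)
})

test_that("junction offsets track planted IR boundaries", {
  cfg <- plastome_config(seed = 3, n_genes = 12, ir_length = 2000,
                         lsc_length = 10000, ssc_length = 5000)
  rec <- simulate_plastome(cfg)
  st <- detect_quadripartite(rec)
  jr <- junction_report(list(st), list(rec))
  expect_setequal(unique(jr$junction), c("JLB", "JSB", "JSA", "JLA"))
  ## plant a gene ending exactly at JSB: offset must be 0
  jsb <- st$irb[2]
  rec2 <- rec
  rec2$features[[1]]$intervals <- matrix(c(jsb - 300L, jsb), 1,
                                         dimnames = list(NULL, c("start", "end")))
  jr2 <- junction_report(list(st), list(rec2))
  expect_equal(jr2$offset_bp[jr2$junction == "JSB"], 0)
  ## a gene spanning the junction reports its overlap
  rec3 <- rec
  rec3$features[[1]]$intervals <- matrix(c(jsb - 100L, jsb + 400L), 1,
                                         dimnames = list(NULL, c("start", "end")))
  jr3 <- junction_report(list(st), list(rec3))
  row <- jr3[jr3$junction == "JSB", ]
  expect_true(row$spans_junction)
  expect_equal(row$offset_bp, 100)
})

test_that("presence/absence flags exactly the planted gene losses", {
  recs <- lapply(1:5, function(i)
    simulate_plastome(plastome_config(
      seed = 100 + i, id = paste0("acc", i), n_genes = 10,
      ir_length = 2000, lsc_length = 10000, ssc_length = 5000,
      delete_gene = if (i == 3) "pg02" else NULL)))
  pa <- presence_absence(recs)
  expect_equal(nrow(pa$loss_events), 1L)
  expect_identical(pa$loss_events$gene, "pg02")
  expect_identical(pa$loss_events$taxon, "acc3")
  ## no deletions: empty loss list
  recs2 <- recs[-3]
  pa2 <- presence_absence(recs2)
  expect_equal(nrow(pa2$loss_events), 0L)
  ## a gene present in only 1 of 5 records yields 4 losses
  rec_extra <- recs[[1]]
  rec_extra$features <- c(rec_extra$features, list(
    list(gene = "unique1", kind = "CDS", strand = "+",
         intervals = matrix(c(0L, 9L), 1))))
  pa3 <- presence_absence(c(list(rec_extra), recs[2:5]))
  expect_equal(sum(pa3$loss_events$gene == "unique1"), 4L)
})
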