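test_that("exon means and splice-flank means aggregate the track", {
  vars <- make_catalog(list(v1 = rbind(c(100, 103), c(200, 300))))
  u <- build_universe(vars)
  track <- tibble::tibble(chrom = "chr13",
                          start = c(98L, 100L, 101L, 102L, 103L, 200L),
                          end = c(100L, 101L, 102L, 103L, 105L, 302L),
                          score = c(0.5, 1, 2, 3, 9, 1.3))
  cons <- exon_conservation(u, track)
  e1 <- cons[cons$exon_number == 1, ]
  expect_equal(e1$mean_score, 2)           # (1 + 2 + 3) / 3
  expect_equal(e1$n_bases, 3)
  expect_equal(e1$flank5_mean, 0.5)        # bases 98-99
  expect_equal(e1$flank3_mean, 9)          # bases 103-104
  e2 <- cons[cons$exon_number == 2, ]
  expect_equal(e2$mean_score, 1.3)
})

test_that("minus-strand flanks follow transcription polarity", {
  vars <- make_catalog(list(v1 = rbind(c(100, 103), c(200, 203))),
                       strand = "-")
  u <- build_universe(vars)
  track <- tibble::tibble(chrom = "chr13", start = c(98L, 100L, 103L),
                          end = c(100L, 103L, 105L),
                          score = c(7, 1, 4))
  cons <- exon_conservation(u, track)
  row <- cons[cons$start == 100, ]
  expect_equal(row$flank5_mean, 4)  # genomic right of the exon
  expect_equal(row$flank3_mean, 7)  # genomic left
})

test_that("track means agree with a naive per-base loop", {
  model <- make_gene(8, seed = 81)
  track <- make_conservation_track(model, noise_sd = 0.3, seed = 81)
  vars <- make_catalog(list(v1 = cbind(model$exons$start, model$exons$end)),
                       chrom = model$chrom)
  u <- build_universe(vars)
  cons <- exon_conservation(u, track)
  for (i in sample(nrow(cons), 4)) {
    expect_equal(cons$mean_score[i],
                 oracle_track_mean(track, cons$start[i], cons$end[i]),
                 tolerance = 1e-12)
  }
})

test_that("zero-noise tracks give every exon exactly the exonic mean", {
  model <- make_gene(6, seed = 82)
  track <- make_conservation_track(model, exon_mean = 1.3, noise_sd = 0,
                                   seed = 82)
  vars <- make_catalog(list(v1 = cbind(model$exons$start, model$exons$end)),
                       chrom = model$chrom)
  cons <- exon_conservation(build_universe(vars), track)
  expect_equal(cons$mean_score, rep(1.3, nrow(cons)))
  expect_true(all(cons$covered))
})

test_that("triplet queries concatenate in-frame peptides in order", {
  # three exons of 30/60/30 nt in frame 0: a 40-aa query
  model <- make_gene(5, seed = 83)
  vars <- make_catalog(list(
    full = cbind(model$exons$start, model$exons$end),
    skip = cbind(model$exons$start[-3], model$exons$end[-3])),
    chrom = model$chrom)
  u <- build_universe(vars)
  ev <- detect_cassettes(u, vars)
  orfs <- find_orfs(c(full = transcript_seq(model, 1:5)), min_aa = 0)
  orfs$variant_id <- "full"
  frames <- orf_frame_map("full", u, orfs)
  q <- build_triplet_queries(ev, u, stats::setNames(model$seq, model$chrom),
                             frames)
  expect_equal(nrow(q), 1)
  trio_len <- sum(model$exons$end[2:4] - model$exons$start[2:4])
  expect_equal(nchar(q$protein), trio_len / 3)
  # the planted peptide appears verbatim in the full protein
  expect_true(grepl(q$protein, orfs$protein[1], fixed = TRUE))
})

test_that("triplet queries skip events with missing frames", {
  model <- make_gene(5, seed = 84)
  vars <- make_catalog(list(
    full = cbind(model$exons$start, model$exons$end),
    skip = cbind(model$exons$start[-3], model$exons$end[-3])),
    chrom = model$chrom)
  u <- build_universe(vars)
  ev <- detect_cassettes(u, vars)
  expect_message(
    q <- build_triplet_queries(ev, u, stats::setNames(model$seq, model$chrom),
                               c(`2` = 0L)),
    "missing frame")
  expect_equal(nrow(q), 0)
})

blast_hit <- function(evalue = 1e-6, qcov = 0.9, pident = 50,
                      gap_fraction = 0.1, sseqid = "human|NM_1",
                      qseqid = "q1") {
  tibble::tibble(qseqid = qseqid, sseqid = sseqid, pident = pident,
                 length = 100L, mismatch = 5L, gapopen = 1L,
                 qstart = 1L, qend = 90L, sstart = 1L, send = 90L,
                 evalue = evalue, bitscore = 100,
                 gap_fraction = gap_fraction, qcov = qcov)
}

test_that("the homology filter applies all four thresholds conjointly", {
  pass <- blast_hit(evalue = 1e-5, qcov = 0.85, pident = 40,
                    gap_fraction = 0.10)
  fail_e <- blast_hit(evalue = 1e-2, qcov = 0.95, pident = 90,
                      gap_fraction = 0)
  out <- filter_blast(dplyr::bind_rows(pass, fail_e))
  expect_equal(out$hits$pass, c(TRUE, FALSE))
})

test_that("filtering equals brute-force predicate conjunction on random hits", {
  set.seed(23)
  hits <- dplyr::bind_rows(lapply(1:20, function(i) {
    blast_hit(evalue = 10^stats::runif(1, -10, 0),
              qcov = stats::runif(1, 0.5, 1),
              pident = stats::runif(1, 10, 100),
              gap_fraction = stats::runif(1, 0, 0.5),
              qseqid = sprintf("q%d", i))
  }))
  got <- filter_blast(hits)$hits$pass
  want <- hits$evalue <= 1e-4 & hits$gap_fraction < 0.30 &
    hits$qcov >= 0.80 & hits$pident >= 30
  expect_equal(got, want)
})

test_that("dropping any one predicate can only grow the passing set", {
  set.seed(29)
  hits <- dplyr::bind_rows(lapply(1:30, function(i) {
    blast_hit(evalue = 10^stats::runif(1, -8, 0),
              qcov = stats::runif(1, 0.5, 1),
              pident = stats::runif(1, 10, 100),
              gap_fraction = stats::runif(1, 0, 0.5),
              qseqid = sprintf("q%d", i))
  }))
  base <- which(filter_blast(hits)$hits$pass)
  relaxed <- list(
    filter_blast(hits, evalue_max = Inf),
    filter_blast(hits, gap_max = Inf),
    filter_blast(hits, qcov_min = 0),
    filter_blast(hits, pident_min = 0))
  for (r in relaxed) expect_true(all(base %in% which(r$hits$pass)))
})

test_that("clade verdicts summarize passing species deterministically", {
  hits <- dplyr::bind_rows(
    blast_hit(sseqid = "human|NM_1", qseqid = "qA"),
    blast_hit(sseqid = "rat|NM_2", qseqid = "qA"),
    blast_hit(sseqid = "zebrafish|NM_3", qseqid = "qA"),
    blast_hit(sseqid = "mouse|NM_4", qseqid = "qB"),
    blast_hit(sseqid = "rat|NM_5", qseqid = "qB"),
    blast_hit(sseqid = "human|NM_6", qseqid = "qC", evalue = 1))
  v <- filter_blast(hits)$verdicts
  expect_equal(v$verdict[v$qseqid == "qA"], "jawed-vertebrate")
  expect_equal(v$verdict[v$qseqid == "qB"], "rodent-only")
  expect_equal(v$verdict[v$qseqid == "qC"], "none")
})
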