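junc_tab <- function(...) {
  rows <- list(...)
  tibble::tibble(
    chrom = "chr13",
    donor = vapply(rows, `[[`, numeric(1), 1),
    acceptor = vapply(rows, `[[`, numeric(1), 2),
    strand = "+",
    support = vapply(rows, function(r) if (length(r) > 2) r[[3]] else 10, numeric(1)))
}

test_that("junctions within the window snap to the supported junction", {
  reads <- make_reads(list(r1 = rbind(c(100, 205), c(398, 600))))
  out <- correct_junctions(reads, junc_tab(c(200, 400)), window = 10)
  expect_equal(out$reads$end[1], 200)
  expect_equal(out$reads$start[2], 400)
  expect_equal(nrow(out$flags), 0)
})

test_that("junctions outside the window stay put and are flagged", {
  reads <- make_reads(list(r1 = rbind(c(100, 215), c(400, 600))))
  out <- correct_junctions(reads, junc_tab(c(200, 400)), window = 10)
  expect_equal(out$reads$end[1], 215)  # donor offset 15 > 10
  expect_equal(out$flags$read_id, "r1")
  expect_equal(out$flags$n_uncorrected, 1L)
})

test_that("correction is idempotent and exact matches pass through", {
  jt <- junc_tab(c(200, 400), c(700, 900))
  reads <- make_reads(list(
    exact = rbind(c(100, 200), c(400, 700), c(900, 1000)),
    wobbly = rbind(c(100, 203), c(396, 705), c(908, 1000))))
  once <- correct_junctions(reads, jt, window = 10)
  expect_equal(once$reads$start[once$reads$read_id == "exact"],
               reads$start[reads$read_id == "exact"])
  twice <- correct_junctions(once$reads, jt, window = 10)
  expect_identical(dplyr::arrange(once$reads, read_id, start),
                   dplyr::arrange(twice$reads, read_id, start))
})

test_that("corrections that collapse an exon exclude the read", {
  # exon [198, 203) shrinks to nothing when both junctions snap
  reads <- make_reads(list(r1 = rbind(c(100, 195), c(198, 203), c(207, 300))))
  out <- correct_junctions(reads, junc_tab(c(196, 202), c(202, 210)),
                           window = 10)
  expect_equal(out$excluded, "r1")
  expect_equal(nrow(out$reads), 0)
})

test_that("equidistant candidates break ties by support then coordinate", {
  # donor 205 is 5 away from both 200 and 210
  reads <- make_reads(list(r1 = rbind(c(100, 205), c(400, 600))))
  jt <- junc_tab(c(200, 400, 5), c(210, 400, 50))
  out <- correct_junctions(reads, jt, window = 10)
  expect_equal(out$reads$end[1], 210)  # higher support wins
  jt_even <- junc_tab(c(200, 400, 50), c(210, 400, 50))
  out2 <- correct_junctions(reads, jt_even, window = 10)
  expect_equal(out2$reads$end[1], 200)  # then smaller coordinate
})

test_that("collapse keeps chains meeting the read-support floor", {
  a <- rbind(c(100, 200), c(400, 500))
  b <- rbind(c(100, 200), c(450, 500))
  reads <- make_reads(list(r1 = a, r2 = a, r3 = a, r4 = b, r5 = b))
  vars <- collapse_reads(reads, min_support = 3)
  expect_equal(nrow(vars), 1)
  expect_equal(vars$chain, "200:400")
  expect_equal(vars$n_reads, 3L)
})

test_that("nearby TSSs cluster into one variant with the modal start", {
  a <- rbind(c(100, 200), c(400, 500))
  a4 <- rbind(c(104, 200), c(400, 500))
  reads <- make_reads(list(r1 = a, r2 = a, r3 = a4, r4 = a4, r5 = a4))
  vars <- collapse_reads(reads, min_support = 3, tss_window = 10)
  expect_equal(nrow(vars), 1)
  expect_equal(vars$tss, 104L)  # modal TSS (3 of 5 reads)
  expect_equal(vars$n_reads, 5L)
})

test_that("collapse output is invariant to read order", {
  s <- small_sim(seed = 21, wobble_prob = 0)
  corr <- correct_junctions(s$sim$reads, s$sim$junctions)
  v1 <- collapse_reads(corr$reads)
  shuffled <- corr$reads[sample(nrow(corr$reads)), ]
  v2 <- collapse_reads(shuffled)
  expect_identical(as.data.frame(v1), as.data.frame(v2))
})

test_that("collapse matches brute-force grouping on tiny read sets", {
  set.seed(99)
  for (trial in 1:8) {
    n_reads <- sample(3:6, 1)
    # reads drawn over a 4-junction scaffold with random chain/TSS jitter
    donors <- c(200, 400, 600, 800)
    acceptors <- donors + 50
    blocks <- lapply(seq_len(n_reads), function(i) {
      k <- sample(1:4, 1)
      use <- sort(sample(4, k))
      starts <- c(100 + sample(0:15, 1), acceptors[use])
      ends <- c(donors[use], 900)
      cbind(starts, ends)
    })
    names(blocks) <- sprintf("r%d", seq_len(n_reads))
    reads <- make_reads(blocks)
    got <- tryCatch(
      collapse_reads(reads, min_support = 2, tss_window = 10),
      error = function(e) NULL)
    want <- oracle_collapse(reads, min_support = 2, tss_window = 10)
    if (is.null(got)) {
      expect_equal(nrow(want), 0)
    } else {
      expect_equal(got$chain, want$chain)
      expect_equal(got$tss, want$tss)
      expect_equal(got$n_reads, want$n_reads)
    }
  }
})

test_that("reads reassign to the nearest chain with deterministic ties", {
  vars <- make_catalog(list(
    X = rbind(c(100, 200), c(300, 400), c(500, 600), c(700, 800)),
    Y = rbind(c(100, 200), c(300, 400), c(500, 600), c(700, 800),
              c(900, 1000))),
    n_reads = c(10L, 5L))
  # truncated read carries X's first two junctions: distance 1 to X
  # (missing 600:700), distance 2 to Y (also missing 800:900) — brute
  # force over both chains
  reads <- make_reads(list(t1 = rbind(c(100, 200), c(300, 400), c(500, 650))))
  q <- quantify_reads(reads, vars, max_dist_frac = 0.6)
  expect_equal(q$assignments$assigned, "X")

  # exact reads -> distance 0
  exact <- make_reads(list(e1 = rbind(c(100, 200), c(300, 400), c(500, 600),
                                      c(700, 800), c(900, 1000))))
  expect_equal(quantify_reads(exact, vars)$assignments$assigned, "Y")
})

test_that("a collapse-retained variant can end with zero quantified reads", {
  vars <- make_catalog(list(
    X = rbind(c(100, 200), c(300, 400)),
    Y = rbind(c(100, 200), c(300, 405))),
    n_reads = c(10L, 3L))
  reads <- make_reads(list(r1 = rbind(c(100, 200), c(300, 400)),
                           r2 = rbind(c(100, 200), c(300, 400))))
  q <- quantify_reads(reads, vars)
  cnt <- dplyr::summarise(dplyr::group_by(q$counts, variant_id),
                          n = sum(count))
  expect_equal(cnt$n[cnt$variant_id == "Y"], 0L)
  expect_true("Y" %in% q$counts$variant_id)
})

test_that("assigned plus removed reads equal input reads per sample", {
  s <- small_sim(seed = 31, wobble_prob = 0.4, skip_prob = 0.05,
                 trunc_prob = 0.2)
  corr <- correct_junctions(s$sim$reads, s$sim$junctions)
  vars <- collapse_reads(corr$reads)
  q <- quantify_reads(corr$reads, vars)
  expect_true(all(q$removed$n_assigned + q$removed$n_removed ==
                    q$removed$n_input))
  expect_equal(sum(q$counts$count), sum(q$removed$n_assigned))
})

test_that("noisy synthetic data collapses back to the exact truth set", {
  model <- make_gene(20, seed = 51)
  truth <- make_truth(model, n_isoforms = 4, seed = 51,
                      wobble_prob = 0.3, wobble_max = 4)
  sim <- simulate_reads(model, truth)
  corr <- correct_junctions(sim$reads, sim$junctions, window = 10)
  vars <- collapse_reads(corr$reads)
  expected <- vapply(truth$isoforms, function(ix) truth_chain(model, ix), "")
  expect_setequal(vars$chain, unname(expected))
})
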