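test_that("find_orf handles stop-terminated and run-through ORFs", {
  s <- paste0("ATG", strrep("GCT", 2999), "TAA")
  orf <- find_orf(s, min_aa = 2000)
  expect_equal(orf$aa_length, 3000)
  expect_true(orf$has_stop)
  expect_equal(substr(orf$protein, 1, 2), "MA")

  s2 <- paste0("ATG", strrep("GCT", 100))
  expect_null(find_orf(s2, min_aa = 2000))
  rec <- find_orf(s2, min_aa = 0)
  expect_equal(rec$aa_length, 101)
  expect_false(rec$has_stop)

  expect_null(find_orf(strrep("GCT", 50), min_aa = 0))  # no ATG
  expect_null(find_orf("", min_aa = 0))
})

test_that("the length gate is strict by default and inclusive on request", {
  s <- paste0("ATG", strrep("GCT", 1999), "TAA")  # exactly 2000 aa
  expect_null(find_orf(s, min_aa = 2000))
  expect_equal(find_orf(s, min_aa = 2000, inclusive = TRUE)$aa_length, 2000)
})

test_that("N-containing codons translate to X and never terminate", {
  s <- paste0("ATG", "TNA", "GCT", "TAA")
  orf <- find_orf(s, min_aa = 0)
  expect_equal(orf$protein, "MXA")
  expect_true(orf$has_stop)
})

test_that("find_orf agrees with a per-ATG brute-force scan", {
  set.seed(7)
  for (trial in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(30:300, 1),
                      replace = TRUE), collapse = "")
    want <- oracle_orf(s)
    got <- find_orf(s, min_aa = 0)
    if (is.null(want) || want$aa == 0) {
      expect_true(is.null(got) || got$aa_length > 0)
    } else {
      expect_equal(got$aa_length, want$aa)
      expect_equal(got$has_stop, want$has_stop)
      # ties broken toward the smallest start offset
      expect_true(got$start_nt <= want$start)
    }
  }
})

pore_hits <- function(ranges, variant_id = "v1", accession = "pfam00520") {
  tibble::tibble(variant_id = variant_id, accession = accession,
                 name = "Ion_trans", aa_from = ranges[, 1],
                 aa_to = ranges[, 2], evalue = 1e-30)
}

test_that("functional calls require both the ORF gate and four pore domains", {
  orfs <- tibble::tibble(variant_id = c("v1", "v2"),
                         start_nt = 0L, end_nt = 6303L,
                         aa_length = c(2100L, 1500L), has_stop = TRUE,
                         protein = "M")
  hits <- dplyr::bind_rows(
    pore_hits(cbind(c(100, 400, 700, 1000), c(300, 600, 900, 1200)), "v1"),
    pore_hits(cbind(c(100, 400, 700, 1000), c(300, 600, 900, 1200)), "v2"))
  calls <- call_functional(orfs, hits)
  expect_true(calls$passes[calls$variant_id == "v1"])
  expect_false(calls$passes[calls$variant_id == "v2"])  # 1500 aa fails
  expect_equal(calls$n_pore_domains, c(4L, 4L))
})

test_that("overlapping pore hits deduplicate to distinct domains", {
  # 5 hits, two of which overlap ~90%: brute-force merge gives 4 domains
  ranges <- cbind(c(100, 400, 410, 700, 1000),
                  c(300, 600, 610, 900, 1200))
  orfs <- tibble::tibble(variant_id = "v1", start_nt = 0L, end_nt = 6303L,
                         aa_length = 2100L, has_stop = TRUE, protein = "M")
  calls <- call_functional(orfs, pore_hits(ranges))
  expect_equal(calls$n_pore_domains, 4L)
  expect_true(calls$passes)
  # disjoint hits stay distinct
  calls2 <- call_functional(
    orfs, pore_hits(cbind(c(100, 400, 700), c(300, 600, 900))))
  expect_equal(calls2$n_pore_domains, 3L)
  expect_false(calls2$passes)
})

test_that("GPHH and IQ domains are flagged but not required", {
  orfs <- tibble::tibble(variant_id = "v1", start_nt = 0L, end_nt = 6303L,
                         aa_length = 2100L, has_stop = TRUE, protein = "M")
  hits <- dplyr::bind_rows(
    pore_hits(cbind(c(100, 400, 700, 1000), c(300, 600, 900, 1200))),
    tibble::tibble(variant_id = "v1", accession = "pfam16905",
                   name = "GPHH", aa_from = 1900L, aa_to = 1950L,
                   evalue = 1e-10))
  calls <- call_functional(orfs, hits)
  expect_true(calls$has_gphh)
  expect_false(calls$has_iq)
  expect_true(calls$passes)
})

test_that("filter gates are monotone in their thresholds", {
  set.seed(13)
  orfs <- tibble::tibble(
    variant_id = sprintf("v%02d", 1:20), start_nt = 0L, end_nt = 9000L,
    aa_length = as.integer(sample(1500:2500, 20)), has_stop = TRUE,
    protein = "M")
  hits <- dplyr::bind_rows(lapply(orfs$variant_id, function(v) {
    k <- sample(2:5, 1)
    starts <- sort(sample(seq(1, 1800, by = 50), k))
    pore_hits(cbind(starts, starts + 150), v)
  }))
  pass_at <- function(min_aa, n_pore) {
    calls <- call_functional(orfs, hits, min_aa = min_aa, n_pore = n_pore)
    calls$variant_id[calls$passes]
  }
  base <- pass_at(2000, 4)
  expect_true(all(base %in% pass_at(1500, 4)))   # lower gate grows the set
  expect_true(all(pass_at(2000, 5) %in% base))   # more pores shrinks it
})
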