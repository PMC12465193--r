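test_that("find_sites extracts the standard donor and acceptor windows", {
  d <- find_sites("AAAGTAAAA")  # GT at 0-based 3, minimal 9-mer
  expect_equal(nrow(d), 1)
  expect_equal(d$site_type, "donor")
  expect_equal(d$position, 3L)
  expect_equal(d$kmer, "AAAGTAAAA")

  acc <- paste0(strrep("C", 18), "AG", "TTT")  # AG at 1-based 19-20
  a <- find_sites(acc)
  expect_equal(nrow(a), 1)
  expect_equal(a$site_type, "acceptor")
  expect_equal(a$position, 18L)
  expect_equal(a$kmer, acc)

  expect_equal(nrow(find_sites("AAAA")), 0)
})

test_that("find_sites equals a regex scan minus boundary-truncated sites", {
  set.seed(31)
  for (trial in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
               collapse = "")
    got <- find_sites(s)
    gt <- gregexpr("GT", s, fixed = TRUE)[[1]]
    gt <- gt[gt != -1 & gt >= 4 & gt + 5 <= nchar(s)]
    ag <- gregexpr("AG", s, fixed = TRUE)[[1]]
    ag <- ag[ag != -1 & ag >= 19 & ag + 4 <= nchar(s)]
    expect_setequal(got$position[got$site_type == "donor"], gt - 1)
    expect_setequal(got$position[got$site_type == "acceptor"], ag - 1)
  }
})

test_that("N-containing k-mers are skipped and counted", {
  s <- "AANGTAAAAAAAGTAAAA"   # first GT window contains N, second is clean
  sites <- find_sites(s)
  expect_equal(attr(sites, "n_skipped"), 1)
  expect_equal(nrow(sites), 1)
})

test_that("a uniform model scores every site zero", {
  m <- uniform_maxent_model()
  expect_equal(score_site("AAAGTAAAA", m, "donor"), 0)
  expect_equal(score_site(paste0(strrep("C", 18), "AGTTT"), m, "acceptor"), 0)
})

test_that("positional model scores equal direct table arithmetic", {
  set.seed(37)
  me <- matrix(stats::runif(36, 0.05, 0.95), nrow = 9,
               dimnames = list(NULL, c("A", "C", "G", "T")))
  null <- matrix(stats::runif(36, 0.05, 0.95), nrow = 9,
                 dimnames = list(NULL, c("A", "C", "G", "T")))
  am <- matrix(0.25, nrow = 23, ncol = 4,
               dimnames = list(NULL, c("A", "C", "G", "T")))
  model <- maxent_model(me, null, am, am)
  kmer <- "ACGGTATCG"
  b <- strsplit(kmer, "")[[1]]
  p_me <- prod(me[cbind(1:9, match(b, c("A", "C", "G", "T")))])
  p_null <- prod(null[cbind(1:9, match(b, c("A", "C", "G", "T")))])
  expect_equal(score_site(kmer, model, "donor"), log2(p_me / p_null),
               tolerance = 1e-12)
})

test_that("explicit-kmer models agree with hand evaluation on all 256 k-mers", {
  # reduced alphabet: vary 4 positions, hold the rest fixed
  set.seed(41)
  fixed_head <- "AC"; fixed_mid <- "GT"; fixed_tail <- "A"
  combos <- expand.grid(b1 = c("A", "C", "G", "T"), b2 = c("A", "C", "G", "T"),
                        b3 = c("A", "C", "G", "T"), b4 = c("A", "C", "G", "T"),
                        stringsAsFactors = FALSE)
  kmers <- paste0(fixed_head, combos$b1, fixed_mid, combos$b2, combos$b3,
                  fixed_tail, combos$b4)
  stopifnot(length(unique(kmers)) == 256, all(nchar(kmers) == 9))
  p_me <- stats::setNames(stats::runif(256, 0.01, 1), kmers)
  p_null <- stats::setNames(stats::runif(256, 0.01, 1), kmers)
  am <- matrix(0.25, nrow = 23, ncol = 4,
               dimnames = list(NULL, c("A", "C", "G", "T")))
  model <- maxent_model(p_me, p_null, am, am)
  for (k in kmers) {
    expect_equal(score_site(k, model, "donor"),
                 log2(p_me[[k]] / p_null[[k]]), tolerance = 1e-9)
  }
})

test_that("doubling a k-mer's foreground probability adds one bit", {
  kmer <- "AAAGTAAAA"
  p_me <- stats::setNames(c(0.2, 0.5), c(kmer, "CCCGTCCCC"))
  p_null <- stats::setNames(c(0.5, 0.5), c(kmer, "CCCGTCCCC"))
  am <- matrix(0.25, nrow = 23, ncol = 4,
               dimnames = list(NULL, c("A", "C", "G", "T")))
  m1 <- maxent_model(p_me, p_null, am, am)
  p_me2 <- p_me; p_me2[kmer] <- 2 * p_me[kmer]
  m2 <- maxent_model(p_me2, p_null, am, am)
  expect_equal(score_site(kmer, m2, "donor") - score_site(kmer, m1, "donor"),
               1, tolerance = 1e-12)
})

test_that("k-mers with N raise an undefined-score error", {
  expect_error(score_site("AANGTAAAA", uniform_maxent_model(), "donor"),
               "N")
})

test_that("catalog scans are ordered and medians match brute force", {
  set.seed(43)
  seqs <- c(
    s1 = paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""),
    s2 = paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""))
  m <- uniform_maxent_model()
  out <- scan_catalog(seqs, m)
  expect_equal(out$sequence_id, sort(out$sequence_id))
  meds <- attr(out, "medians")
  for (ty in c("donor", "acceptor")) {
    sc <- sort(out$score[out$site_type == ty])
    want <- if (length(sc) %% 2 == 1) sc[(length(sc) + 1) / 2]
            else mean(sc[length(sc) / 2 + 0:1])
    expect_equal(unname(meds[ty]), want)
  }
  expect_warning(empty <- scan_catalog(character(), m), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("model tables round-trip through their on-disk layout", {
  set.seed(47)
  mk <- function(k) {
    m <- matrix(stats::runif(4 * k, 0.05, 0.95), nrow = k,
                dimnames = list(NULL, c("A", "C", "G", "T")))
    m
  }
  model <- maxent_model(mk(9), mk(9), mk(23), mk(23), provenance = "test")
  dir <- withr::local_tempdir()
  write_maxent_tables(model, dir)
  back <- read_maxent_tables(dir)
  kmer <- "ACGGTATCG"
  expect_equal(score_site(kmer, back, "donor"),
               score_site(kmer, model, "donor"), tolerance = 1e-9)
})

test_that("model validation rejects bad shapes and probabilities", {
  am <- matrix(0.25, nrow = 23, ncol = 4,
               dimnames = list(NULL, c("A", "C", "G", "T")))
  dm <- matrix(0.25, nrow = 9, ncol = 4,
               dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_error(maxent_model(am, am, am, am), "9 x 4")
  bad <- dm; bad[1, 1] <- 0
  expect_error(maxent_model(bad, dm, am, am), "probabilities")
})
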