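# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive: they re-derive expected results by enumeration so
# the implementation under test is checked against a second, simpler
# route.

# Block-level read tibble from a list of exon-block matrices
# (list(read_id = rbind(c(start, end), ...))).
make_reads <- function(blocks, sample_id = "s1", chrom = "chr13",
                       strand = "+") {
  rows <- lapply(names(blocks), function(id) {
    b <- blocks[[id]]
    tibble::tibble(read_id = id, sample_id = sample_id, chrom = chrom,
                   strand = strand, start = b[, 1], end = b[, 2],
                   block = seq_len(nrow(b)))
  })
  dplyr::bind_rows(rows)
}

# A splice_catalog tibble straight from exon-block matrices.
make_catalog <- function(blocks, chrom = "chr13", strand = "+",
                         n_reads = NULL) {
  rows <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    chain <- if (nrow(b) > 1) {
      paste(paste(b[-nrow(b), 2], b[-1, 1], sep = ":"), collapse = ";")
    } else ""
    tibble::tibble(
      variant_id = names(blocks)[i], chrom = chrom, strand = strand,
      tss = b[1, 1], tes = b[nrow(b), 2], chain = chain,
      n_exons = nrow(b),
      n_reads = if (is.null(n_reads)) 10L else n_reads[i])
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("splice_catalog", class(out))
  out
}

# Brute-force collapse: group reads by exact junction chain, then
# single-linkage TSS clustering within a group, modal TSS/TES, support
# filter. Returns a sorted tibble of (chain, tss, n_reads).
oracle_collapse <- function(reads, min_support = 3, tss_window = 10) {
  chains <- isocat:::reads_to_chains(reads)
  chains <- chains[chains$n_blocks > 1, ]
  out <- list()
  for (key in unique(chains$chain)) {
    g <- chains[chains$chain == key, ]
    g <- g[order(g$tss), ]
    cluster <- 1L
    cl <- integer(nrow(g))
    cl[1] <- 1L
    if (nrow(g) > 1) for (i in 2:nrow(g)) {
      if (g$tss[i] - g$tss[i - 1] > tss_window) cluster <- cluster + 1L
      cl[i] <- cluster
    }
    for (c in unique(cl)) {
      sub <- g[cl == c, ]
      if (nrow(sub) < min_support) next
      modal <- function(x) {
        tt <- table(x)
        as.integer(names(tt)[which.max(tt)])
      }
      out[[length(out) + 1]] <- tibble::tibble(
        chain = key, tss = modal(sub$tss), tes = modal(sub$tes),
        n_reads = nrow(sub))
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chain = character(), tss = integer(),
                          tes = integer(), n_reads = integer()))
  }
  dplyr::bind_rows(out) |> dplyr::arrange(tss, tes, chain)
}

# Brute-force cassette enumeration over all (a, e, b) exon triples.
oracle_cassettes <- function(universe, variants) {
  seqs <- lapply(split(universe$membership, universe$membership$variant_id),
                 function(m) m$exon_number[order(m$position)])
  exon_nums <- universe$exons$exon_number
  found <- list()
  for (a in exon_nums) for (e in exon_nums) for (b in exon_nums) {
    has_in <- vapply(seqs, function(s) {
      any(vapply(seq_len(max(0, length(s) - 2)), function(i)
        s[i] == a && s[i + 1] == e && s[i + 2] == b, logical(1)))
    }, logical(1))
    has_out <- vapply(seqs, function(s) {
      any(vapply(seq_len(max(0, length(s) - 1)), function(i)
        s[i] == a && s[i + 1] == b, logical(1)))
    }, logical(1))
    if (any(has_in) && any(has_out)) {
      found[[length(found) + 1]] <- e
    }
  }
  sort(unique(as.integer(unlist(found))))
}

# Direct per-base track mean over [start, end).
oracle_track_mean <- function(track, start, end) {
  vals <- rep(NA_real_, end - start)
  for (i in seq_len(nrow(track))) {
    lo <- max(track$start[i], start); hi <- min(track$end[i], end)
    if (hi > lo) vals[(lo - start + 1):(hi - start)] <- track$score[i]
  }
  mean(vals[!is.na(vals)])
}

# Independent ORF scan: try every ATG, translate naively.
oracle_orf <- function(seq) {
  n <- nchar(seq)
  best <- NULL
  for (p in seq_len(max(0, n - 2))) {
    if (substr(seq, p, p + 2) != "ATG") next
    aa <- 0L; has_stop <- FALSE
    q <- p
    while (q + 2 <= n) {
      codon <- substr(seq, q, q + 2)
      if (codon %in% c("TAA", "TAG", "TGA")) { has_stop <- TRUE; break }
      aa <- aa + 1L
      q <- q + 3
    }
    if (is.null(best) || aa > best$aa) {
      best <- list(start = p - 1L, aa = aa, has_stop = has_stop)
    }
  }
  best
}

# Tiny gene/truth/sim bundle reused by several tests.
small_sim <- function(n_exons = 12, seed = 42, ...) {
  model <- make_gene(n_exons, seed = seed)
  truth <- make_truth(model, n_isoforms = 3, seed = seed, ...)
  sim <- simulate_reads(model, truth)
  list(model = model, truth = truth, sim = sim)
}

# Junction chain of an isoform (exon indices) in a gene model.
truth_chain <- function(model, exon_idx) {
  b <- model$exons[sort(exon_idx), ]
  if (nrow(b) < 2) return("")
  paste(paste(b$end[-nrow(b)], b$start[-1], sep = ":"), collapse = ";")
}
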