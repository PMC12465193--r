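#' Correct read splice junctions against short-read junction support
#'
#' Each read junction absent from the support table is replaced by the
#' nearest table junction whose donor and acceptor are both within
#' `window` nt (total donor+acceptor offset minimized; ties broken toward
#' higher short-read support, then smaller donor coordinate). Junctions
#' with no table junction in range are left unchanged and flagged.
#' Corrections adjust the flanking block boundaries; a correction that
#' would create an empty or negative-length exon marks the read unusable
#' and excludes it.
#'
#' The operation is idempotent: corrected junctions are table junctions
#' and are never moved again.
#'
#' @param reads Block-level read tibble (`read_id`, `sample_id`, `chrom`,
#'   `strand`, `start`, `end`).
#' @param junctions Junction support table (`chrom`, `donor`, `acceptor`,
#'   `strand`, `support`).
#' @param window Maximum per-endpoint offset in nt (default 10, the
#'   standard long-read correction window).
#' @return A list: `reads` (corrected block tibble), `flags` (tibble
#'   `read_id`, `n_uncorrected`), `excluded` (read ids dropped as
#'   unusable).
#' @export
correct_junctions <- function(reads, junctions, window = 10) {
  if (window < 0) stop("window must be >= 0", call. = FALSE)
  if (nrow(reads) == 0) {
    return(list(reads = reads,
                flags = tibble::tibble(read_id = character(),
                                       n_uncorrected = integer()),
                excluded = character()))
  }
  reads <- dplyr::arrange(reads, .data$read_id, .data$start)
  n <- nrow(reads)
  # rows i and i+1 of the same read flank junction (end[i], start[i+1])
  jrow <- which(reads$read_id[-n] == reads$read_id[-1L])
  if (length(jrow) == 0L) {
    return(list(reads = reads,
                flags = tibble::tibble(read_id = character(),
                                       n_uncorrected = integer()),
                excluded = character()))
  }
  jx <- tibble::tibble(
    row = jrow, read_id = reads$read_id[jrow],
    chrom = reads$chrom[jrow], strand = reads$strand[jrow],
    donor = reads$end[jrow], acceptor = reads$start[jrow + 1L])

  # resolve each distinct observed junction once, then map back
  uniq <- dplyr::distinct(jx, .data$chrom, .data$strand, .data$donor,
                          .data$acceptor)
  jt <- split(seq_len(nrow(junctions)),
              paste(junctions$chrom, junctions$strand))
  res_d <- uniq$donor; res_a <- uniq$acceptor
  res_unc <- logical(nrow(uniq))
  tkey <- paste(junctions$chrom, junctions$strand, junctions$donor,
                junctions$acceptor)
  ukey <- paste(uniq$chrom, uniq$strand, uniq$donor, uniq$acceptor)
  exact <- ukey %in% tkey
  for (i in which(!exact)) {
    idx <- jt[[paste(uniq$chrom[i], uniq$strand[i])]]
    cand <- idx[abs(junctions$donor[idx] - uniq$donor[i]) <= window &
                  abs(junctions$acceptor[idx] - uniq$acceptor[i]) <= window]
    if (length(cand) == 0L) {
      res_unc[i] <- TRUE
      next
    }
    off <- abs(junctions$donor[cand] - uniq$donor[i]) +
      abs(junctions$acceptor[cand] - uniq$acceptor[i])
    best <- cand[order(off, -junctions$support[cand],
                       junctions$donor[cand])[1]]
    res_d[i] <- junctions$donor[best]
    res_a[i] <- junctions$acceptor[best]
  }
  hit <- match(paste(jx$chrom, jx$strand, jx$donor, jx$acceptor), ukey)
  reads$end[jx$row] <- res_d[hit]
  reads$start[jx$row + 1L] <- res_a[hit]
  uncorrected <- res_unc[hit]

  # exclude reads whose corrected blocks collapse or overlap
  bad_len <- reads$end - reads$start <= 0
  bad_ord <- c(FALSE, reads$read_id[-n] == reads$read_id[-1L] &
                 reads$start[-1L] < reads$end[-n])
  excluded <- unique(reads$read_id[bad_len | bad_ord])
  flags <- jx |>
    dplyr::mutate(unc = uncorrected) |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(n_uncorrected = sum(.data$unc), .groups = "drop") |>
    dplyr::filter(.data$n_uncorrected > 0)
  list(
    reads = reads[!reads$read_id %in% excluded, ],
    flags = flags,
    excluded = excluded
  )
}

#' Collapse corrected reads into splice variants
#'
#' Reads are grouped by (chrom, strand, exact junction chain); within a
#' group, transcription start sites are clustered by single linkage with
#' gap <= `tss_window` and each cluster becomes a candidate variant whose
#' reported TSS is the cluster's modal read start (ties toward the
#' smallest). Mono-exonic reads are excluded (a targeted amplicon spans
#' many exons). Candidates supported by fewer than `min_support` reads
#' pooled across samples are discarded. The variant's transcript end is
#' the modal read end. Variant ids are assigned deterministically in
#' genomic order, so the output is invariant to read order.
#'
#' @param reads Corrected block-level read tibble.
#' @param min_support Minimum pooled read support (default 3).
#' @param tss_window TSS clustering window in nt (default 10).
#' @return A `splice_catalog` tibble: `variant_id`, `chrom`, `strand`,
#'   `tss`, `tes`, `chain`, `n_exons`, `n_reads` (pooled collapse-stage
#'   support), plus attribute `read_assignments` mapping reads to the
#'   variant they collapsed into.
#' @export
collapse_reads <- function(reads, min_support = 3, tss_window = 10) {
  chains <- reads_to_chains(reads) |>
    dplyr::filter(.data$n_blocks > 1L)
  if (nrow(chains) == 0) {
    stop("no multi-exonic reads to collapse", call. = FALSE)
  }
  modal <- function(x) {
    ux <- sort(unique(x))
    ux[which.max(tabulate(match(x, ux)))]  # ties -> smallest value
  }
  groups <- split(seq_len(nrow(chains)),
                  paste(chains$chrom, chains$strand, chains$chain,
                        sep = "\r"))
  rows <- list()
  for (idx in groups) {
    g_tss <- chains$tss[idx]
    o <- order(g_tss)
    idx <- idx[o]; g_tss <- g_tss[o]
    cl <- cumsum(c(1L, diff(g_tss) > tss_window))
    for (c_id in unique(cl)) {
      sub <- idx[cl == c_id]
      if (length(sub) < min_support) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = chains$chrom[sub[1]], strand = chains$strand[sub[1]],
        chain = chains$chain[sub[1]],
        tss = modal(chains$tss[sub]), tes = modal(chains$tes[sub]),
        n_reads = length(sub), read_ids = list(chains$read_id[sub]))
    }
  }
  if (length(rows) == 0L) {
    stop("no variants pass the read-support floor", call. = FALSE)
  }
  cand <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$chrom, .data$tss, .data$tes, .data$chain) |>
    dplyr::mutate(variant_id = sprintf("V%04d", dplyr::row_number()),
                  n_exons = stringr::str_count(.data$chain, ";") + 2L -
                    (.data$chain == ""))
  assignments <- cand |>
    dplyr::select("variant_id", "read_ids") |>
    tidyr::unnest_longer("read_ids", values_to = "read_id") |>
    dplyr::left_join(dplyr::distinct(chains, .data$read_id, .data$sample_id),
                     by = "read_id")
  out <- cand |>
    dplyr::select("variant_id", "chrom", "strand", "tss", "tes", "chain",
                  "n_exons", "n_reads")
  attr(out, "read_assignments") <- assignments
  class(out) <- c("splice_catalog", class(out))
  out
}

#' Exon blocks of each variant in a catalog
#'
#' @param variants A `splice_catalog` tibble.
#' @return Long tibble `variant_id`, `chrom`, `strand`, `start`, `end`,
#'   one row per exon block in genomic order.
#' @export
variant_exons <- function(variants) {
  purrr::pmap(list(variants$variant_id, variants$chrom, variants$strand,
                   variants$tss, variants$tes, variants$chain),
              function(v, c, s, tss, tes, chain) {
    b <- blocks_from_chain(tss, tes, chain)
    tibble::tibble(variant_id = v, chrom = c, strand = s,
                   start = b$start, end = b$end)
  }) |>
    dplyr::bind_rows()
}

junction_distance <- function(chain_a, chain_b) {
  a <- strsplit(chain_a, ";", fixed = TRUE)[[1]]
  b <- strsplit(chain_b, ";", fixed = TRUE)[[1]]
  length(setdiff(a, b)) + length(setdiff(b, a))
}

#' Quantify variants by read reassignment
#'
#' Every multi-exonic read is reassigned to the retained variant with the
#' minimal junction-chain distance (the number of junctions present in
#' exactly one of the two chains); ties go to the variant with more
#' collapse-stage support, then the smaller variant id. Reads whose best
#' distance exceeds `max_dist_frac` of their own junction count are left
#' unassigned and reported as removed — so a variant retained at collapse
#' can end with zero reads, and assigned + removed reads always equal the
#' input reads per sample.
#'
#' @param reads Corrected block-level read tibble.
#' @param variants A `splice_catalog` from [collapse_reads()].
#' @param max_dist_frac Assignment cap as a fraction of the read's
#'   junction count (default 0.25).
#' @return List: `counts` (tibble `variant_id`, `sample_id`, `count`,
#'   complete over all variants and samples), `removed` (tibble
#'   `sample_id`, `n_removed`), `assignments`.
#' @export
quantify_reads <- function(reads, variants, max_dist_frac = 0.25) {
  chains <- reads_to_chains(reads)
  samples <- sort(unique(chains$sample_id))
  by_read <- chains |> dplyr::filter(.data$n_blocks > 1L)

  # index variants by chrom/strand once; pre-split their junction chains
  vkey <- paste(variants$chrom, variants$strand)
  vjunc <- strsplit(variants$chain, ";", fixed = TRUE)
  vlen <- lengths(vjunc)
  assign_chain <- function(chain, key) {
    idx <- which(vkey == key)
    if (length(idx) == 0) return(NA_character_)
    a <- strsplit(chain, ";", fixed = TRUE)[[1]]
    # |A \ B| + |B \ A| = |A| + |B| - 2|A intersect B|
    d <- vapply(idx, function(i)
      length(a) + vlen[i] - 2 * sum(a %in% vjunc[[i]]), numeric(1))
    ord <- order(d, -variants$n_reads[idx], variants$variant_id[idx])
    best <- ord[1]
    if (d[best] > max_dist_frac * length(a)) NA_character_
    else variants$variant_id[idx[best]]
  }
  # resolve each distinct read chain once
  uniq <- dplyr::distinct(by_read, .data$chrom, .data$strand, .data$chain)
  ukey <- paste(uniq$chrom, uniq$strand, uniq$chain)
  res <- vapply(seq_len(nrow(uniq)), function(i)
    assign_chain(uniq$chain[i], paste(uniq$chrom[i], uniq$strand[i])),
    character(1))
  by_read$assigned <- res[match(paste(by_read$chrom, by_read$strand,
                                      by_read$chain), ukey)]

  assigned <- by_read |> dplyr::filter(!is.na(.data$assigned))
  counts <- assigned |>
    dplyr::count(variant_id = .data$assigned, .data$sample_id,
                 name = "count") |>
    tidyr::complete(variant_id = variants$variant_id,
                    sample_id = samples, fill = list(count = 0L))
  n_input <- chains |> dplyr::count(.data$sample_id, name = "n_input")
  n_assigned <- assigned |> dplyr::count(.data$sample_id, name = "n_assigned")
  removed <- n_input |>
    dplyr::left_join(n_assigned, by = "sample_id") |>
    dplyr::mutate(n_assigned = dplyr::coalesce(.data$n_assigned, 0L),
                  n_removed = .data$n_input - .data$n_assigned)
  list(counts = counts,
       removed = dplyr::select(removed, "sample_id", "n_removed", "n_input",
                               "n_assigned"),
       assignments = dplyr::select(by_read, "read_id", "sample_id",
                                   "assigned"))
}
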