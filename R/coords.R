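# Internal coordinate helpers. Every interval in memory is 0-based
# half-open (BED convention); a splice junction is (donor, acceptor) where
# donor = 0-based position of the first intronic base and acceptor = one
# past the last intronic base. A junction chain is serialized as
# "donor:acceptor;donor:acceptor;..." in genomic order so it can be used
# as a grouping key.

chain_encode <- function(donors, acceptors) {
  if (length(donors) == 0L) return("")
  paste(paste(donors, acceptors, sep = ":"), collapse = ";")
}

chain_decode <- function(chain) {
  if (is.na(chain) || chain == "") {
    return(tibble::tibble(donor = integer(), acceptor = integer()))
  }
  parts <- strsplit(strsplit(chain, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  tibble::tibble(
    donor = vapply(parts, function(p) as.integer(p[[1]]), integer(1)),
    acceptor = vapply(parts, function(p) as.integer(p[[2]]), integer(1))
  )
}

# Exon blocks [start, end) of a transcript model given tss/tes and its
# junction chain. With k junctions there are k + 1 exons.
blocks_from_chain <- function(tss, tes, chain) {
  j <- chain_decode(chain)
  tibble::tibble(start = c(tss, j$acceptor), end = c(j$donor, tes))
}

# Per-read summary of a block-level alignment tibble: TSS, TES and the
# serialized junction chain. Input must be sorted by block start within
# each read (read_bed12 and simulate_reads guarantee this).
reads_to_chains <- function(reads) {
  reads <- dplyr::arrange(reads, .data$read_id, .data$start)
  n <- nrow(reads)
  if (n == 0L) {
    return(tibble::tibble(read_id = character(), sample_id = character(),
                          chrom = character(), strand = character(),
                          tss = integer(), tes = integer(),
                          n_blocks = integer(), chain = character()))
  }
  new_read <- c(TRUE, reads$read_id[-1L] != reads$read_id[-n])
  grp <- cumsum(new_read)
  first <- which(new_read)
  last <- c(first[-1L] - 1L, n)
  # junction between consecutive rows of the same read
  jrow <- which(reads$read_id[-n] == reads$read_id[-1L])
  jstr <- paste0(reads$end[jrow], ":", reads$start[jrow + 1L])
  chains <- character(length(first))
  has_j <- tabulate(grp[jrow], nbins = length(first)) > 0
  chains[has_j] <- vapply(split(jstr, grp[jrow]), paste, collapse = ";",
                          FUN.VALUE = "")
  tibble::tibble(
    read_id = reads$read_id[first],
    sample_id = reads$sample_id[first],
    chrom = reads$chrom[first],
    strand = reads$strand[first],
    tss = reads$start[first],
    tes = reads$end[last],
    n_blocks = last - first + 1L,
    chain = chains)
}

# Validate a block tibble: sorted, non-overlapping, positive length.
check_blocks <- function(blocks, what = "blocks") {
  if (any(blocks$end <= blocks$start)) {
    stop(sprintf("%s: empty or negative-length interval", what), call. = FALSE)
  }
  if (nrow(blocks) > 1L && any(diff(blocks$start) <= 0 |
        blocks$start[-1] < blocks$end[-nrow(blocks)])) {
    stop(sprintf("%s: blocks must be sorted and non-overlapping", what),
         call. = FALSE)
  }
  invisible(blocks)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
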