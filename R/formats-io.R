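#' Read a BED12 file of read or transcript structures
#'
#' Parses a 12-column BED file into a block-level tibble, one row per exon
#' block, with absolute 0-based half-open coordinates. The name column may
#' carry a sample tag as `"read_id|sample_id"`; the part after the first
#' `|` is split into `sample_id` (otherwise `NA`).
#'
#' @param path Path to a BED12 file.
#' @return A tibble with columns `read_id`, `sample_id`, `chrom`, `strand`,
#'   `start`, `end` and `block` (1-based block index within the record),
#'   in file order.
#' @export
read_bed12 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(
      read_id = character(), sample_id = character(), chrom = character(),
      strand = character(), start = integer(), end = integer(),
      block = integer()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1]
    stop(sprintf("BED12 parse error at line %d: %d columns (expected 12)",
                 bad, nf[bad]), call. = FALSE)
  }
  recs <- purrr::imap(fields, function(f, i) {
    chrom_start <- as.integer(f[2]); chrom_end <- as.integer(f[3])
    n_blocks <- as.integer(f[10])
    sizes <- as.integer(strsplit(f[11], ",", fixed = TRUE)[[1]])
    starts <- as.integer(strsplit(f[12], ",", fixed = TRUE)[[1]])
    if (length(sizes) != n_blocks || length(starts) != n_blocks) {
      stop(sprintf("BED12 validation error at line %d: blockCount %d but %d sizes / %d starts",
                   i, n_blocks, length(sizes), length(starts)), call. = FALSE)
    }
    if (n_blocks > 1L && any(diff(starts) <= 0)) {
      stop(sprintf("BED12 validation error at line %d: blockStarts not ascending",
                   i), call. = FALSE)
    }
    if (starts[1] != 0L || chrom_start + starts[n_blocks] + sizes[n_blocks] != chrom_end) {
      stop(sprintf("BED12 validation error at line %d: blocks inconsistent with chromStart/chromEnd",
                   i), call. = FALSE)
    }
    name <- strsplit(f[4], "|", fixed = TRUE)[[1]]
    tibble::tibble(
      read_id = name[1],
      sample_id = if (length(name) > 1L) name[2] else NA_character_,
      chrom = f[1], strand = f[6],
      start = chrom_start + starts,
      end = chrom_start + starts + sizes,
      block = seq_len(n_blocks)
    )
  })
  dplyr::bind_rows(recs)
}

#' Write read or transcript structures as BED12
#'
#' Inverse of [read_bed12()]: block-level tibbles are serialized one BED12
#' record per `read_id`, with the sample tag (when present) appended to the
#' name as `"read_id|sample_id"`. Round-trips coordinates and block
#' structure exactly.
#'
#' @param reads Block-level tibble as returned by [read_bed12()] or
#'   [simulate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(reads, path) {
  recs <- reads |>
    dplyr::arrange(factor(.data$read_id, levels = unique(.data$read_id)),
                   .data$start) |>
    dplyr::group_by(.data$read_id, .data$sample_id, .data$chrom, .data$strand) |>
    dplyr::summarise(
      chrom_start = min(.data$start), chrom_end = max(.data$end),
      n = dplyr::n(),
      sizes = paste(.data$end - .data$start, collapse = ","),
      starts = paste(.data$start - min(.data$start), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::mutate(name = ifelse(is.na(.data$sample_id), .data$read_id,
                                paste(.data$read_id, .data$sample_id, sep = "|")))
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
                   recs$chrom, recs$chrom_start, recs$chrom_end, recs$name,
                   recs$strand, recs$chrom_start, recs$chrom_end,
                   recs$n, recs$sizes, recs$starts)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a short-read splice-junction support table
#'
#' Reads an `SJ.out.tab`-style table (tab-separated: chrom, 1-based
#' inclusive intron start, 1-based inclusive intron end, strand code, then
#' either a count column or the STAR layout whose 7th column is the
#' uniquely-mapping read count). Coordinates are converted to the internal
#' 0-based half-open convention: `donor` is the first intronic base,
#' `acceptor` one past the last. Duplicate junctions have their supports
#' summed; zero-support rows are dropped with a warning.
#'
#' @param path Path to the junction table.
#' @return A tibble `chrom`, `donor`, `acceptor`, `strand`, `support`.
#' @export
read_junction_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(chrom = character(), donor = integer(),
                          acceptor = integer(), strand = character(),
                          support = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L)) {
    bad <- which(nf < 5L)[1]
    stop(sprintf("junction table parse error at line %d: %d columns (expected >= 5)",
                 bad, nf[bad]), call. = FALSE)
  }
  count_col <- ifelse(nf >= 7L, 7L, 5L)
  tab <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    istart = as.integer(vapply(fields, `[[`, "", 2L)),
    iend = as.integer(vapply(fields, `[[`, "", 3L)),
    strand_code = vapply(fields, `[[`, "", 4L),
    support = as.integer(purrr::map2_chr(fields, count_col, `[[`))
  )
  if (any(is.na(tab$support)) || any(tab$support < 0)) {
    stop("junction table validation error: negative or non-numeric counts",
         call. = FALSE)
  }
  if (any(tab$iend < tab$istart)) {
    stop("junction table validation error: intron end before intron start",
         call. = FALSE)
  }
  n_zero <- sum(tab$support == 0)
  if (n_zero > 0) {
    warning(sprintf("dropping %d junction row(s) with zero support", n_zero),
            call. = FALSE)
  }
  tab |>
    dplyr::filter(.data$support > 0) |>
    dplyr::mutate(
      strand = dplyr::case_when(
        .data$strand_code %in% c("1", "+") ~ "+",
        .data$strand_code %in% c("2", "-") ~ "-",
        TRUE ~ "*"
      ),
      donor = .data$istart - 1L,
      acceptor = .data$iend
    ) |>
    dplyr::group_by(.data$chrom, .data$donor, .data$acceptor, .data$strand) |>
    dplyr::summarise(support = sum(.data$support), .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$donor, .data$acceptor)
}

#' Read a conserved-domain (CDD-style) hit table
#'
#' Accepts the tabular hit layout of CDD batch searches: columns query,
#' hit type, accession (e.g. `pfam00520`), from, to, e-value, name (e.g.
#' `Ion_trans`). Both tab- and comma-separated files are tolerated. Query
#' ids are normalized by dropping anything after the first whitespace and
#' stripping an ORF-tool suffix matched by `id_strip`.
#'
#' @param path Path to the hit table.
#' @param id_strip Regex removed from the end of each query id
#'   (default strips TransDecoder-style `".p1"` suffixes).
#' @return A tibble `variant_id`, `accession`, `name`, `aa_from`, `aa_to`,
#'   `evalue`.
#' @export
read_domain_table <- function(path, id_strip = "\\.p\\d+$") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(tibble::tibble(variant_id = character(), accession = character(),
                          name = character(), aa_from = integer(),
                          aa_to = integer(), evalue = double()))
  }
  sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(lengths(fields) < 7L)
  if (length(bad) > 0) {
    stop(sprintf("domain table parse error: %d row(s) with < 7 columns (first at line %d)",
                 length(bad), bad[1]), call. = FALSE)
  }
  out <- tibble::tibble(
    variant_id = vapply(fields, `[[`, "", 1L),
    accession = vapply(fields, `[[`, "", 3L),
    aa_from = suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L))),
    aa_to = suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L))),
    evalue = suppressWarnings(as.double(vapply(fields, `[[`, "", 6L))),
    name = vapply(fields, `[[`, "", 7L)
  )
  bad_coord <- which(is.na(out$aa_from) | is.na(out$aa_to) | out$aa_from > out$aa_to)
  if (length(bad_coord) > 0) {
    stop(sprintf("domain table validation error: unparseable or inverted protein coordinates in %d row(s) (first at line %d)",
                 length(bad_coord), bad_coord[1]), call. = FALSE)
  }
  out |>
    dplyr::mutate(
      variant_id = sub("\\s.*$", "", .data$variant_id),
      variant_id = sub(id_strip, "", .data$variant_id),
      variant_id = sub("^Q#\\d+ - >", "", .data$variant_id)
    ) |>
    dplyr::select("variant_id", "accession", "name", "aa_from", "aa_to", "evalue")
}

#' Read BLAST tabular (outfmt 6) hits
#'
#' Parses the 12 standard columns and derives `qcov` (query coverage,
#' alignment span on the query over the query length, when `query_lengths`
#' is given) and `gap_fraction` (alignment columns gapped on the query over
#' alignment length).
#'
#' @param path Path to an outfmt-6 file.
#' @param query_lengths Optional named vector of query lengths (aa for
#'   tBLASTn) used to compute `qcov`.
#' @return A tibble with the standard columns (`qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`) plus `gap_fraction` and (optionally)
#'   `qcov`.
#' @export
read_blast_tab <- function(path, query_lengths = NULL) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  hits <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                          col_types = "ccdiiiiiiidd", comment = "#")
  if (any(hits$pident < 0 | hits$pident > 100)) {
    stop("BLAST table validation error: percent identity outside [0, 100]",
         call. = FALSE)
  }
  if (any(hits$evalue < 0)) {
    stop("BLAST table validation error: negative e-value", call. = FALSE)
  }
  hits <- hits |>
    dplyr::mutate(gap_fraction =
      (.data$length - (abs(.data$qend - .data$qstart) + 1L)) / .data$length)
  if (!is.null(query_lengths)) {
    hits <- hits |>
      dplyr::mutate(qcov = (abs(.data$qend - .data$qstart) + 1L) /
                      unname(query_lengths[.data$qseqid]))
  }
  hits
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, one sequence per record.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a basewise conservation track from bedGraph
#'
#' Intervals are kept run-length encoded (`chrom`, `start`, `end`,
#' `score`); downstream aggregation intersects intervals instead of
#' expanding per-base vectors.
#'
#' @param path Path to a bedGraph file.
#' @return A tibble `chrom`, `start`, `end`, `score` (0-based half-open).
#' @export
read_conservation_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    score = gr$score
  )
}

#' Write a conservation track as bedGraph
#'
#' @param track Tibble `chrom`, `start`, `end`, `score` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation_bedgraph <- function(track, path) {
  readr::write_lines(sprintf("%s\t%d\t%d\t%g", track$chrom, track$start,
                             track$end, track$score), path)
  invisible(path)
}

#' Read exon intervals from a GTF/GFF annotation
#'
#' Keeps rows of feature type `exon` only and converts them to the
#' internal 0-based half-open convention.
#'
#' @param path Path to a GTF or GFF file.
#' @return A tibble `chrom`, `start`, `end`, `strand` (one row per exon).
#' @export
read_gtf_exons <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "exon"]
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Read a counts matrix in long or wide CSV layout
#'
#' A wide layout (first column variant ids, remaining columns one per
#' sample) is pivoted to the long form used throughout the package.
#'
#' @param path Path to a CSV counts file.
#' @return A tibble `variant_id`, `sample_id`, `count`.
#' @export
read_counts_csv <- function(path) {
  wide <- readr::read_csv(path, show_col_types = FALSE)
  names(wide)[1] <- "variant_id"
  long <- wide |>
    tidyr::pivot_longer(-"variant_id", names_to = "sample_id",
                        values_to = "count")
  if (any(long$count < 0)) {
    stop("counts validation error: negative counts", call. = FALSE)
  }
  long
}
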