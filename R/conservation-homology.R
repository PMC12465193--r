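# Weighted mean of a run-length-encoded track over [start, end);
# returns mean and number of covered bases.
interval_track_mean <- function(track, chrom, start, end) {
  seg <- track[track$chrom == chrom & track$end > start & track$start < end, ]
  if (nrow(seg) == 0) return(c(mean = NA_real_, n = 0))
  w <- pmin(seg$end, end) - pmax(seg$start, start)
  c(mean = sum(seg$score * w) / sum(w), n = sum(w))
}

#' Aggregate basewise conservation per exon and splice-site flank
#'
#' Computes the arithmetic mean of a conservation track over each universe
#' exon, and over the two intronic bases adjacent to the exon's 5' and 3'
#' sides (the splice-site dinucleotide flanks). Flanks follow transcription
#' polarity: on `-` strand exons the 5' flank is genomic-right. Exons with
#' no covered base get `NA` means and are flagged.
#'
#' @param universe An `exon_universe` from [build_universe()].
#' @param track Conservation tibble (`chrom`, `start`, `end`, `score`),
#'   e.g. from [read_conservation_bedgraph()].
#' @param track_name Label recorded in the output (e.g. `"phyloP"`).
#' @return Tibble `exon_number`, `start`, `end`, `mean_score`, `n_bases`,
#'   `flank5_mean`, `flank3_mean`, `track_name`, `covered`.
#' @export
exon_conservation <- function(universe, track, track_name = "phyloP") {
  ex <- universe$exons
  rows <- purrr::pmap(list(ex$exon_number, ex$chrom, ex$start, ex$end),
                      function(num, chrom, s, e) {
    body <- interval_track_mean(track, chrom, s, e)
    left <- interval_track_mean(track, chrom, s - 2L, s)
    right <- interval_track_mean(track, chrom, e, e + 2L)
    if (universe$strand == "-") { tmp <- left; left <- right; right <- tmp }
    tibble::tibble(exon_number = num, start = s, end = e,
                   mean_score = body[["mean"]], n_bases = body[["n"]],
                   flank5_mean = left[["mean"]], flank3_mean = right[["mean"]])
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(track_name = track_name, covered = .data$n_bases > 0)
}

#' Build triplet-exon peptide queries for homology search
#'
#' For each cassette event, extracts the upstream-flank, cassette and
#' downstream-flank exon sequences strand-aware, translates each in its
#' supplied reading frame, and concatenates the peptides in transcription
#' order — the query used to test whether the exon trio is present in
#' other species' transcribed sequences. Events with a missing frame for
#' any component exon are skipped with a message.
#'
#' @param events Tibble from [detect_cassettes()].
#' @param universe The `exon_universe`.
#' @param genome Named character vector chrom -> sequence.
#' @param frame_map Named integer vector exon_number -> frame (0, 1 or 2:
#'   bases to skip at the exon's transcription-order start before the
#'   first complete codon), typically derived from the passing ORF.
#' @return Tibble `exon_number`, `query_id`, `protein`, `source_exons`
#'   (list-column of the three exon numbers).
#' @export
build_triplet_queries <- function(events, universe, genome, frame_map) {
  ex <- universe$exons
  exon_seq <- function(num) {
    row <- ex[ex$exon_number == num, ]
    s <- substr(genome[[row$chrom]], row$start + 1L, row$end)
    if (universe$strand == "-") reverse_complement(s) else s
  }
  translate_in_frame <- function(seq, frame) {
    seq <- substr(seq, frame + 1L, nchar(seq))
    n_codons <- nchar(seq) %/% 3L
    if (n_codons == 0L) return("")
    cpos <- 3L * (seq_len(n_codons) - 1L) + 1L
    paste(translate_codons(substring(seq, cpos, cpos + 2L)), collapse = "")
  }
  rows <- purrr::pmap(list(events$exon_number, events$upstream_exon,
                           events$downstream_exon),
                      function(e, up, down) {
    trio <- c(up, e, down)
    if (!all(as.character(trio) %in% names(frame_map))) {
      message(sprintf("skipping event exon %d: missing frame for a component exon", e))
      return(NULL)
    }
    peptides <- vapply(trio, function(x)
      translate_in_frame(exon_seq(x), frame_map[[as.character(x)]]), "")
    tibble::tibble(exon_number = e,
                   query_id = sprintf("cassette_%d_trio_%d_%d_%d", e, up, e, down),
                   protein = paste(peptides, collapse = ""),
                   source_exons = list(trio))
  })
  dplyr::bind_rows(rows)
}

#' Reading frames of universe exons under a variant's ORF
#'
#' Maps the ORF of one variant onto the exon universe: each exon the ORF
#' covers gets the frame offset (0/1/2) at which translation enters the
#' exon in transcription order.
#'
#' @param variant_id Variant whose ORF anchors the frames.
#' @param universe The `exon_universe`.
#' @param orfs Tibble from [find_orfs()].
#' @return Named integer vector exon_number -> frame.
#' @export
orf_frame_map <- function(variant_id, universe, orfs) {
  orf <- orfs[orfs$variant_id == variant_id, ]
  if (nrow(orf) == 0) stop("no ORF for variant ", variant_id, call. = FALSE)
  mem <- universe$membership[universe$membership$variant_id == variant_id, ]
  mem <- mem[order(mem$position), ]
  ex <- universe$exons
  lens <- ex$end[match(mem$exon_number, ex$exon_number)] -
    ex$start[match(mem$exon_number, ex$exon_number)]
  tx_start <- cumsum(c(0L, lens[-length(lens)]))  # transcript offset of exon
  # frame = bases to skip at the exon's transcription-order start: to the
  # ORF start when it lies inside the exon, else to the next codon boundary
  frames <- integer(0)
  for (i in seq_along(lens)) {
    s <- tx_start[i]; e <- s + lens[i]
    if (e <= orf$start_nt || s >= orf$end_nt) next
    key <- as.character(mem$exon_number[i])
    frames[key] <- if (orf$start_nt > s) as.integer(orf$start_nt - s)
                   else as.integer((3L - (s - orf$start_nt) %% 3L) %% 3L)
  }
  frames
}

#' Filter BLAST tabular hits with conservation thresholds
#'
#' A hit passes iff `evalue <= evalue_max` AND `gap_fraction < gap_max`
#' AND `qcov >= qcov_min` AND `pident >= pident_min` (defaults: 1e-4,
#' 0.30, 0.80, 30 — the standard conservative homology filter). The
#' filter is a pure conjunction, so relaxing any one threshold can only
#' grow the passing set. Per query, passing hits are summarized into a
#' phylogenetic verdict via a species -> clade map.
#'
#' @param hits Tibble from [read_blast_tab()] (needs `qcov`; computed
#'   here when `query_lengths` is given).
#' @param query_lengths Optional named vector of query lengths.
#' @param evalue_max,gap_max,qcov_min,pident_min Thresholds.
#' @param species_map Named vector subject-species -> clade; the species
#'   tag is the part of `sseqid` before the first `|` or `_`. Defaults to
#'   [default_clade_map()].
#' @return List: `hits` (input plus `species`, `clade`, `pass`),
#'   `verdicts` (tibble `qseqid`, `clades`, `verdict`).
#' @export
filter_blast <- function(hits, query_lengths = NULL, evalue_max = 1e-4,
                         gap_max = 0.30, qcov_min = 0.80, pident_min = 30,
                         species_map = default_clade_map()) {
  if (!"qcov" %in% names(hits)) {
    if (is.null(query_lengths)) {
      stop("qcov absent: supply query_lengths", call. = FALSE)
    }
    hits <- hits |>
      dplyr::mutate(qcov = (abs(.data$qend - .data$qstart) + 1L) /
                      unname(query_lengths[.data$qseqid]))
  }
  out <- hits |>
    dplyr::mutate(
      species = sub("[|_].*$", "", .data$sseqid),
      clade = unname(species_map[.data$species]),
      pass = .data$evalue <= evalue_max & .data$gap_fraction < gap_max &
        .data$qcov >= qcov_min & .data$pident >= pident_min
    )
  verdicts <- out |>
    dplyr::filter(.data$pass) |>
    dplyr::group_by(.data$qseqid) |>
    dplyr::summarise(clades = list(sort(unique(stats::na.omit(.data$clade)))),
                     .groups = "drop") |>
    dplyr::mutate(verdict = purrr::map_chr(.data$clades, clade_verdict))
  verdicts <- tibble::tibble(qseqid = unique(out$qseqid)) |>
    dplyr::left_join(verdicts, by = "qseqid") |>
    dplyr::mutate(clades = purrr::map(.data$clades, ~ if (is.null(.x)) character() else .x),
                  verdict = dplyr::coalesce(.data$verdict, "none"))
  list(hits = out, verdicts = verdicts)
}

clade_verdict <- function(clades) {
  if (length(clades) == 0) return("none")
  has_fish <- any(clades %in% c("fish", "jawless_fish"))
  has_rodent <- "rodent" %in% clades
  has_primate <- "primate" %in% clades
  if (has_fish && (has_rodent || has_primate)) return("jawed-vertebrate")
  if (has_rodent && has_primate) return("mammal")
  if (has_rodent) return("rodent-only")
  if (has_primate) return("primate-only")
  if (has_fish) return("fish-only")
  "other"
}

#' Default species-to-clade map for homology verdicts
#'
#' Covers the species panel used for triplet-exon homology searches.
#'
#' @return Named character vector species -> clade.
#' @export
default_clade_map <- function() {
  c(human = "primate", mouse = "rodent", rat = "rodent",
    zebrafish = "fish", fugu = "fish", coelacanth = "fish",
    gar = "fish", lamprey = "jawless_fish")
}
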