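#' Build the exon universe of a variant catalog
#'
#' Reduces all variants to their exons, deduplicates by exact coordinates,
#' assigns stable exon numbers in transcription order (genomic order on
#' `+`, reversed on `-`), records per-variant membership, and flags as
#' novel every exon not entirely contained within some reference exon.
#'
#' @param variants A `splice_catalog` tibble (one chrom/strand).
#' @param reference_exons Optional reference annotation tibble (`start`,
#'   `end`, same chrom); `NULL` or empty marks every exon novel.
#' @return An `exon_universe`: list with `exons` (tibble `exon_number`,
#'   `chrom`, `strand`, `start`, `end`, `novel`) and `membership` (tibble
#'   `variant_id`, `exon_number`, `position` — position is the exon's
#'   1-based index along the variant in transcription order).
#' @export
build_universe <- function(variants, reference_exons = NULL) {
  if (length(unique(variants$chrom)) > 1L ||
      length(unique(variants$strand)) > 1L) {
    stop("variants must be on a single chrom and strand", call. = FALSE)
  }
  minus <- variants$strand[1] == "-"
  vx <- variant_exons(variants)
  exons <- vx |>
    dplyr::distinct(.data$chrom, .data$strand, .data$start, .data$end) |>
    dplyr::arrange(if (minus) -.data$start else .data$start) |>
    dplyr::mutate(exon_number = dplyr::row_number(), .before = 1)
  novel <- rep(TRUE, nrow(exons))
  if (!is.null(reference_exons) && nrow(reference_exons) > 0) {
    for (i in seq_len(nrow(exons))) {
      novel[i] <- !any(reference_exons$start <= exons$start[i] &
                         exons$end[i] <= reference_exons$end)
    }
  }
  exons$novel <- novel
  membership <- vx |>
    dplyr::left_join(dplyr::select(exons, "exon_number", "start", "end"),
                     by = c("start", "end")) |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::arrange(if (minus) -.data$start else .data$start,
                   .by_group = TRUE) |>
    dplyr::mutate(position = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("variant_id", "exon_number", "position")
  structure(list(exons = exons, membership = membership,
                 strand = variants$strand[1]),
            class = "exon_universe")
}

#' @export
print.exon_universe <- function(x, ...) {
  cat(sprintf("<exon_universe> %d exons (%d novel), %d variants\n",
              nrow(x$exons), sum(x$exons$novel),
              length(unique(x$membership$variant_id))))
  invisible(x)
}

#' Detect cassette-exon events
#'
#' Exon `e` is a cassette exon iff some variant carries consecutive exons
#' `(a, e, b)` while another carries `(a, b)` consecutively — identical
#' flanking exons by exact coordinates, with the skipped form's junction
#' joining `a`'s end directly to `b`'s start. One event is reported per
#' exon; containing/lacking variant sets collect every variant exhibiting
#' either configuration for any qualifying flank pair. Exons differing at
#' either boundary are distinct, so alternative 5'/3' splice-site usage
#' never produces an event.
#'
#' @param universe An `exon_universe` from [build_universe()].
#' @param variants The `splice_catalog` the universe was built from.
#' @return Tibble: `exon_number`, `start`, `end`, `upstream_exon`,
#'   `downstream_exon`, `containing` and `lacking` (list-columns of
#'   variant ids), `n_containing`, `n_lacking`.
#' @export
detect_cassettes <- function(universe, variants) {
  if (nrow(variants) < 2L) {
    stop("cassette detection needs at least 2 variants", call. = FALSE)
  }
  seqs <- universe$membership |>
    dplyr::arrange(.data$variant_id, .data$position) |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(s = list(.data$exon_number), .groups = "drop")
  chains <- stats::setNames(seqs$s, seqs$variant_id)

  # adjacent pairs and triples across all variants
  pair_rows <- purrr::imap(chains, function(s, v) {
    if (length(s) < 2L) return(NULL)
    tibble::tibble(variant_id = v, a = s[-length(s)], b = s[-1L])
  }) |> dplyr::bind_rows()
  triple_rows <- purrr::imap(chains, function(s, v) {
    if (length(s) < 3L) return(NULL)
    tibble::tibble(variant_id = v, a = s[1:(length(s) - 2L)],
                   e = s[2:(length(s) - 1L)], b = s[3:length(s)])
  }) |> dplyr::bind_rows()
  if (nrow(triple_rows) == 0) return(empty_cassette_tbl())

  hits <- triple_rows |>
    dplyr::inner_join(pair_rows, by = c("a", "b"),
                      suffix = c("_in", "_out"),
                      relationship = "many-to-many") |>
    dplyr::filter(.data$variant_id_in != .data$variant_id_out)
  if (nrow(hits) == 0) return(empty_cassette_tbl())

  events <- hits |>
    dplyr::group_by(.data$e) |>
    dplyr::summarise(
      upstream_exon = min(.data$a),
      downstream_exon = .data$b[which.min(.data$a)][1],
      containing = list(sort(unique(.data$variant_id_in))),
      lacking = list(sort(unique(.data$variant_id_out))),
      .groups = "drop") |>
    dplyr::rename(exon_number = "e") |>
    dplyr::left_join(dplyr::select(universe$exons, "exon_number", "start",
                                   "end"),
                     by = "exon_number") |>
    dplyr::mutate(n_containing = lengths(.data$containing),
                  n_lacking = lengths(.data$lacking)) |>
    dplyr::arrange(.data$exon_number) |>
    dplyr::select("exon_number", "start", "end", "upstream_exon",
                  "downstream_exon", "containing", "lacking",
                  "n_containing", "n_lacking")
  events
}

empty_cassette_tbl <- function() {
  tibble::tibble(exon_number = integer(), start = integer(), end = integer(),
                 upstream_exon = integer(), downstream_exon = integer(),
                 containing = list(), lacking = list(),
                 n_containing = integer(), n_lacking = integer())
}

#' Read fractions per cassette event
#'
#' For each event, the fraction of reads lacking the exon among reads
#' assigned to the containing or lacking variants, after restricting both
#' sets to `universe_filter` (typically the channel-forming variant set,
#' the context in which skipped-read percentages are reported). Events
#' whose lacking (or containing) set empties after filtering are dropped
#' with a warning.
#'
#' @param events Tibble from [detect_cassettes()].
#' @param counts Long counts tibble (`variant_id`, `sample_id`, `count`).
#' @param universe_filter Optional character vector of variant ids
#'   restricting the denominator (default: all variants in `counts`).
#' @return `events` with `reads_containing`, `reads_lacking` and
#'   `fraction_reads_lacking` columns.
#' @export
event_read_fractions <- function(events, counts, universe_filter = NULL) {
  pooled <- counts |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(n = sum(.data$count), .groups = "drop")
  pool <- stats::setNames(pooled$n, pooled$variant_id)
  keep_set <- if (is.null(universe_filter)) names(pool) else universe_filter

  out <- events |>
    dplyr::mutate(
      containing = purrr::map(.data$containing, intersect, keep_set),
      lacking = purrr::map(.data$lacking, intersect, keep_set),
      reads_containing = purrr::map_dbl(.data$containing,
                                        ~ sum(pool[.x], na.rm = TRUE)),
      reads_lacking = purrr::map_dbl(.data$lacking,
                                     ~ sum(pool[.x], na.rm = TRUE)),
      n_containing = lengths(.data$containing),
      n_lacking = lengths(.data$lacking),
      fraction_reads_lacking = .data$reads_lacking /
        (.data$reads_containing + .data$reads_lacking)
    )
  empty <- out$n_containing == 0 | out$n_lacking == 0
  if (any(empty)) {
    warning(sprintf("%d event(s) dropped: containing or lacking set empty after filtering",
                    sum(empty)), call. = FALSE)
    out <- out[!empty, ]
  }
  out
}
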