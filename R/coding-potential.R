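translate_codons <- function(codons) {
  lut <- Biostrings::GENETIC_CODE
  aa <- unname(lut[codons])
  aa[is.na(aa)] <- "X"  # codons containing N (or partial) -> X, never stop
  aa[aa == "*"] <- "*"
  aa
}

#' Predict the longest ATG-initiated open reading frame
#'
#' Scans all three frames of the sense strand only (the amplicon is
#' strand-defined). The ORF starts at an `ATG` and runs to the first
#' in-frame stop codon, or to the transcript end when no stop occurs
#' (`has_stop = FALSE`) — a start codon is required, a stop codon is not.
#' Codons containing `N` translate to `X` and never terminate the ORF.
#' The longest qualifying ORF wins; ties go to the smallest start offset.
#'
#' @param transcript Nucleotide sequence over `{A,C,G,T,N}`.
#' @param min_aa Minimum amino-acid length (default 2000, the length a
#'   functional four-domain channel protein requires); shorter ORFs return
#'   `NULL`.
#' @param inclusive If `FALSE` (default) the gate is strict
#'   (`aa_length > min_aa`); if `TRUE`, `aa_length >= min_aa`.
#' @return A one-row tibble `start_nt`, `end_nt`, `aa_length`, `has_stop`,
#'   `protein`, or `NULL` if no qualifying ORF exists.
#' @export
find_orf <- function(transcript, min_aa = 2000, inclusive = FALSE) {
  if (is.null(transcript) || is.na(transcript) || nchar(transcript) < 3L) {
    return(NULL)
  }
  s <- toupper(transcript)
  n <- nchar(s)
  chars <- strsplit(s, "")[[1]]
  starts <- which(chars == "A")
  starts <- starts[starts + 2L <= n &
                     chars[starts + 1L] == "T" & chars[starts + 2L] == "G"]
  if (length(starts) == 0) return(NULL)

  best <- NULL
  for (p in starts) {  # p: 1-based position of A
    n_codons <- (n - p + 1L) %/% 3L
    if (n_codons < 1L) next
    cpos <- p + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(s, cpos, cpos + 2L)
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    stop_at <- which(is_stop)
    if (length(stop_at) > 0) {
      aa_len <- stop_at[1] - 1L
      has_stop <- TRUE
      if (aa_len == 0L) next  # ATG immediately... impossible (ATG != stop)
      prot_codons <- codons[seq_len(aa_len)]
      end_nt <- (p - 1L) + 3L * stop_at[1]  # one past last codon incl. stop
    } else {
      aa_len <- n_codons
      has_stop <- FALSE
      prot_codons <- codons
      end_nt <- (p - 1L) + 3L * n_codons
    }
    if (is.null(best) || aa_len > best$aa_length) {
      best <- tibble::tibble(
        start_nt = p - 1L, end_nt = end_nt, aa_length = aa_len,
        has_stop = has_stop,
        protein = paste(translate_codons(prot_codons), collapse = ""))
    }
  }
  if (is.null(best)) return(NULL)
  keep <- if (inclusive) best$aa_length >= min_aa else best$aa_length > min_aa
  if (!keep) NULL else best
}

#' ORF prediction across a variant catalog
#'
#' @param transcripts Named character vector (variant_id -> transcript
#'   sequence).
#' @param min_aa,inclusive As in [find_orf()].
#' @return Tibble `variant_id`, `start_nt`, `end_nt`, `aa_length`,
#'   `has_stop`, `protein` — one row per variant with a qualifying ORF.
#' @export
find_orfs <- function(transcripts, min_aa = 2000, inclusive = FALSE) {
  purrr::imap(transcripts, function(s, id) {
    rec <- find_orf(s, min_aa = min_aa, inclusive = inclusive)
    if (is.null(rec)) NULL else dplyr::mutate(rec, variant_id = id,
                                              .before = 1)
  }) |>
    dplyr::bind_rows()
}

# Count distinct pore domains after merging hits that overlap more than
# `overlap_frac` of the shorter hit (connected components of the overlap
# graph): CDD can emit both specific and superfamily rows for one domain.
dedup_pore_count <- function(aa_from, aa_to, overlap_frac = 0.5) {
  n <- length(aa_from)
  if (n == 0) return(0L)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ov <- min(aa_to[i], aa_to[j]) - max(aa_from[i], aa_from[j]) + 1L
    shorter <- min(aa_to[i] - aa_from[i], aa_to[j] - aa_from[j]) + 1L
    if (ov > overlap_frac * shorter) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) comp[rj] <- ri
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Call channel-forming potential per variant
#'
#' A variant passes when its predicted ORF clears the length gate and its
#' deduplicated pore-forming domain (pfam00520) count reaches `n_pore`:
#' the four homologous transmembrane repeats are all required for calcium
#' passage. GPHH (pfam16905) and IQ (pfam08763) calmodulin-regulation
#' domains are flagged but not required.
#'
#' @param orfs Tibble from [find_orfs()] (variants without a row fail).
#' @param hits Domain-hit tibble (`variant_id`, `accession`, `aa_from`,
#'   `aa_to`, ...).
#' @param min_aa ORF length gate in aa (default 2000).
#' @param n_pore Required pore-domain count (default 4).
#' @param inclusive Length-gate comparator, as in [find_orf()].
#' @param overlap_frac Two pore hits overlapping more than this fraction
#'   of the shorter hit count once (default 0.5).
#' @return Tibble `variant_id`, `aa_length`, `n_pore_domains`, `has_gphh`,
#'   `has_iq`, `passes` — one row per variant appearing in `orfs` or
#'   `hits`.
#' @export
call_functional <- function(orfs, hits, min_aa = 2000, n_pore = 4,
                            inclusive = FALSE, overlap_frac = 0.5) {
  ids <- union(orfs$variant_id, hits$variant_id)
  pore <- hits |>
    dplyr::filter(.data$accession == "pfam00520") |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(n_pore_domains =
      dedup_pore_count(.data$aa_from, .data$aa_to, overlap_frac),
      .groups = "drop")
  out <- tibble::tibble(variant_id = sort(ids)) |>
    dplyr::left_join(dplyr::select(orfs, "variant_id", "aa_length"),
                     by = "variant_id") |>
    dplyr::left_join(pore, by = "variant_id") |>
    dplyr::mutate(
      n_pore_domains = as.integer(dplyr::coalesce(.data$n_pore_domains, 0L)),
      has_gphh = .data$variant_id %in%
        hits$variant_id[hits$accession == "pfam16905"],
      has_iq = .data$variant_id %in%
        hits$variant_id[hits$accession == "pfam08763"],
      len_ok = !is.na(.data$aa_length) &
        (if (inclusive) .data$aa_length >= min_aa
         else .data$aa_length > min_aa),
      passes = .data$len_ok & .data$n_pore_domains >= n_pore
    ) |>
    dplyr::select("variant_id", "aa_length", "n_pore_domains", "has_gphh",
                  "has_iq", "passes")
  out
}
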