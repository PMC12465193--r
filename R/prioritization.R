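#' Rank variants by pooled expression and compute expression ratios
#'
#' Pooled counts are row sums across samples. Ranks are assigned over
#' descending pooled counts with ties broken toward the smaller variant
#' id, so rank 1 is the most expressed variant. The expression ratio of a
#' variant is the rank-1 variant's pooled count divided by its own (1.0
#' for the rank-1 variant, `Inf` for zero-count variants); a ratio below
#' 2 means the variant is expressed at >= 50% of the rank-1 variant — the
#' "appreciably expressed" criterion. `share` is the variant's fraction of
#' total gene expression. Per-sample ranks are computed the same way
#' within each sample.
#'
#' @param counts Long counts tibble (`variant_id`, `sample_id`, `count`,
#'   optionally `tpm`).
#' @param ratio_threshold Prioritization threshold on the expression ratio
#'   (default 2).
#' @param strict If `TRUE` (default) prioritized means `ratio <
#'   ratio_threshold`, else `<=`.
#' @return Tibble sorted by rank: `variant_id`, `pooled_count`, `rank`,
#'   `expression_ratio`, `share`, `prioritized`, plus list-column-free
#'   per-sample ranks in attribute `per_sample_rank` (tibble `variant_id`,
#'   `sample_id`, `rank`).
#' @export
rank_and_ratio <- function(counts, ratio_threshold = 2, strict = TRUE) {
  pooled <- counts |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(pooled_count = sum(.data$count), .groups = "drop")
  if (all(pooled$pooled_count == 0)) {
    stop("all-zero counts matrix", call. = FALSE)
  }
  top <- max(pooled$pooled_count)
  recs <- pooled |>
    dplyr::arrange(dplyr::desc(.data$pooled_count), .data$variant_id) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      expression_ratio = ifelse(.data$pooled_count == 0, Inf,
                                top / .data$pooled_count),
      share = .data$pooled_count / sum(.data$pooled_count),
      prioritized = if (strict) .data$expression_ratio < ratio_threshold
                    else .data$expression_ratio <= ratio_threshold
    )
  per_sample <- counts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$variant_id,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("variant_id", "sample_id", "rank")
  attr(recs, "per_sample_rank") <- per_sample
  recs
}

#' Length-normalize counts to transcripts per million
#'
#' Per sample, `tpm_i = (c_i / l_i) / sum_j (c_j / l_j) * 1e6`, so TPM
#' sums to one million in every sample with nonzero counts. Samples with
#' all-zero counts yield all-zero TPM with a warning.
#'
#' @param counts Long counts tibble (`variant_id`, `sample_id`, `count`).
#' @param lengths Named vector: variant_id -> transcript length in nt.
#' @return `counts` with a `tpm` column; attribute `spearman_counts_tpm`
#'   holds the Spearman correlation between pooled raw counts and pooled
#'   TPM (a library-size-normalization robustness diagnostic).
#' @export
compute_tpm <- function(counts, lengths) {
  nz <- counts |> dplyr::filter(.data$count > 0)
  missing <- setdiff(unique(nz$variant_id), names(lengths))
  if (length(missing) > 0) {
    stop("missing transcript length for variant(s) with nonzero counts: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  if (any(lengths[unique(nz$variant_id)] <= 0)) {
    stop("non-positive transcript length", call. = FALSE)
  }
  out <- counts |>
    dplyr::mutate(rate = .data$count / unname(lengths[.data$variant_id])) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(tpm = if (sum(.data$rate) == 0) 0 else
      .data$rate / sum(.data$rate) * 1e6) |>
    dplyr::ungroup() |>
    dplyr::select(-"rate")
  zero_samples <- out |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(z = all(.data$count == 0), .groups = "drop")
  if (any(zero_samples$z)) {
    warning("sample(s) with all-zero counts yield all-zero TPM: ",
            paste(zero_samples$sample_id[zero_samples$z], collapse = ", "),
            call. = FALSE)
  }
  pooled <- out |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(c = sum(.data$count), t = sum(.data$tpm),
                     .groups = "drop")
  attr(out, "spearman_counts_tpm") <-
    suppressWarnings(stats::cor(pooled$c, pooled$t, method = "spearman"))
  out
}

#' Summarize how much expression the functional variant set captures
#'
#' @param records Tibble from [rank_and_ratio()].
#' @param functional_calls Tibble from [call_functional()] (uses `passes`).
#' @param top_k How many top ranks to itemize (default 10).
#' @return List: `functional_share` (fraction of total expression from
#'   passing variants), `top_shares` (tibble `rank`, `variant_id`,
#'   `share`, `passes`), `per_sample_rank` (from the records attribute).
#' @export
expression_summary <- function(records, functional_calls, top_k = 10) {
  passing <- functional_calls$variant_id[functional_calls$passes]
  list(
    functional_share = sum(records$share[records$variant_id %in% passing]),
    top_shares = records |>
      dplyr::slice_min(.data$rank, n = top_k) |>
      dplyr::mutate(passes = .data$variant_id %in% passing) |>
      dplyr::select("rank", "variant_id", "share", "passes"),
    per_sample_rank = attr(records, "per_sample_rank")
  )
}
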