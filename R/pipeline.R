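#' Run the full catalog-and-prioritize analysis
#'
#' Executes the stages in order — junction correction, collapse,
#' quantification, ORF prediction, functional calling, expression
#' prioritization, cassette-event detection (+ read fractions),
#' per-exon conservation, and splice-site scoring — from a single config
#' list. Any stage whose inputs are supplied precomputed is skipped.
#' Returns a machine-readable funnel report (variant counts surviving
#' each filter) alongside all stage outputs.
#'
#' @param config Named list. File inputs: `reads_bed`, `junctions_sj`,
#'   `genome_fasta`, `reference_gtf`, `conservation_bedgraph`,
#'   `domains_table`, `maxent_dir`; or in-memory equivalents `reads`,
#'   `junctions`, `genome` (named chrom->sequence), `reference_exons`,
#'   `conservation`, `domains`, `maxent_model`. Parameters (all optional):
#'   `window` (10), `min_support` (3), `tss_window` (10),
#'   `max_dist_frac` (0.25), `min_aa` (2000), `inclusive_min_aa` (FALSE),
#'   `n_pore` (4), `ratio_threshold` (2), `seed` (1).
#' @return An `isocat_report`: list with `funnel` (tibble `stage`, `n`),
#'   `variants`, `counts`, `removed`, `orfs`, `functional`, `priority`,
#'   `universe`, `events`, `conservation`, `sites`, `config`.
#' @export
run_pipeline <- function(config) {
  p <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  set.seed(p("seed", 1))

  need <- function(obj_name, file_name, reader, stage) {
    if (!is.null(config[[obj_name]])) return(config[[obj_name]])
    if (!is.null(config[[file_name]])) return(reader(config[[file_name]]))
    stop(sprintf("stage '%s': missing mandatory input '%s' (or '%s')",
                 stage, obj_name, file_name), call. = FALSE)
  }
  opt <- function(obj_name, file_name, reader) {
    if (!is.null(config[[obj_name]])) return(config[[obj_name]])
    if (!is.null(config[[file_name]])) return(reader(config[[file_name]]))
    NULL
  }

  # collapse (+ correction) ---------------------------------------------
  if (!is.null(config$variants)) {
    variants <- config$variants
    reads <- opt("reads", "reads_bed", read_bed12)
  } else {
    reads <- need("reads", "reads_bed", read_bed12, "collapse")
    junctions <- need("junctions", "junctions_sj", read_junction_table,
                      "collapse")
    corr <- correct_junctions(reads, junctions, window = p("window", 10))
    reads <- corr$reads
    variants <- collapse_reads(reads, min_support = p("min_support", 3),
                               tss_window = p("tss_window", 10))
  }

  # quantify -------------------------------------------------------------
  if (!is.null(config$counts)) {
    counts <- config$counts; removed <- NULL
  } else {
    if (is.null(reads)) stop("stage 'quantify': missing reads", call. = FALSE)
    q <- quantify_reads(reads, variants,
                        max_dist_frac = p("max_dist_frac", 0.25))
    counts <- q$counts; removed <- q$removed
  }

  # ORF + functional ------------------------------------------------------
  genome <- opt("genome", "genome_fasta", read_fasta)
  if (!is.null(config$orfs)) {
    orfs <- config$orfs
  } else {
    if (is.null(genome)) stop("stage 'orf': missing genome", call. = FALSE)
    vx <- variant_exons(variants)
    tx <- split(vx, vx$variant_id)
    seqs <- vapply(tx, function(b) {
      b <- b[order(b$start), ]
      s <- paste(substring(genome[[b$chrom[1]]], b$start + 1L, b$end),
                 collapse = "")
      if (b$strand[1] == "-") reverse_complement(s) else s
    }, "")
    orfs <- find_orfs(seqs, min_aa = p("min_aa", 2000),
                      inclusive = p("inclusive_min_aa", FALSE))
  }
  domains <- opt("domains", "domains_table", read_domain_table)
  if (is.null(domains)) {
    domains <- scan_marker_domains(stats::setNames(orfs$protein,
                                                   orfs$variant_id))
  }
  functional <- call_functional(orfs, domains, min_aa = p("min_aa", 2000),
                                n_pore = p("n_pore", 4),
                                inclusive = p("inclusive_min_aa", FALSE))

  # prioritize ------------------------------------------------------------
  priority <- rank_and_ratio(counts,
                             ratio_threshold = p("ratio_threshold", 2))

  # events ----------------------------------------------------------------
  reference <- opt("reference_exons", "reference_gtf", read_gtf_exons)
  universe <- build_universe(variants, reference)
  passing <- functional$variant_id[functional$passes]
  events <- detect_cassettes(universe, variants)
  if (nrow(events) > 0) {
    events <- suppressWarnings(
      event_read_fractions(events, counts,
                           universe_filter = if (length(passing) > 0)
                             passing else NULL))
  }

  # conservation ----------------------------------------------------------
  track <- opt("conservation", "conservation_bedgraph",
               read_conservation_bedgraph)
  conservation <- if (!is.null(track)) exon_conservation(universe, track)
                  else NULL

  # splice-site scoring ---------------------------------------------------
  memodel <- opt("maxent_model", "maxent_dir", read_maxent_tables)
  sites <- NULL
  if (!is.null(memodel) && !is.null(genome)) {
    vx <- variant_exons(variants)
    tx <- split(vx, vx$variant_id)
    seqs <- vapply(tx, function(b) {
      b <- b[order(b$start), ]
      s <- paste(substring(genome[[b$chrom[1]]], b$start + 1L, b$end),
                 collapse = "")
      if (b$strand[1] == "-") reverse_complement(s) else s
    }, "")
    sites <- scan_catalog(seqs[passing[passing %in% names(seqs)]], memodel)
  }

  funnel <- tibble::tibble(
    stage = c("input_reads", "collapsed_variants", "orf_pass",
              "functional_pass", "prioritized"),
    n = c(if (!is.null(reads)) length(unique(reads$read_id)) else NA_integer_,
          nrow(variants), nrow(orfs), sum(functional$passes),
          sum(priority$prioritized)))

  structure(list(
    funnel = funnel, variants = variants, counts = counts,
    removed = removed, orfs = orfs, functional = functional,
    priority = priority, universe = universe, events = events,
    conservation = conservation, sites = sites, config = config
  ), class = "isocat_report")
}

#' @export
print.isocat_report <- function(x, ...) {
  cat("<isocat_report>\n")
  print(x$funnel)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the stage funnel of a pipeline report
#'
#' @param x An `isocat_report`.
#' @param ... Ignored.
#' @return The funnel tibble (`stage`, `n`).
#' @export
tidy.isocat_report <- function(x, ...) x$funnel

#' One-row summary of a pipeline report
#'
#' @param x An `isocat_report`.
#' @param ... Ignored.
#' @return One-row tibble with variant counts at each stage, number of
#'   cassette events and the functional expression share.
#' @export
glance.isocat_report <- function(x, ...) {
  summ <- expression_summary(x$priority, x$functional)
  tibble::tibble(
    n_variants = nrow(x$variants),
    n_orf_pass = nrow(x$orfs),
    n_functional = sum(x$functional$passes),
    n_prioritized = sum(x$priority$prioritized),
    n_cassette_events = if (is.null(x$events)) 0L else nrow(x$events),
    functional_share = summ$functional_share)
}

#' Expression-rank overview plot for a pipeline report
#'
#' Shares of total gene expression by expression rank, colored by whether
#' the variant passes the channel-forming filter.
#'
#' @param object An `isocat_report`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.isocat_report <- function(object, ...) {
  passing <- object$functional$variant_id[object$functional$passes]
  df <- object$priority |>
    dplyr::mutate(functional = .data$variant_id %in% passing)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$share,
                                   fill = .data$functional)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#17becf",
                                          `FALSE` = "#d62728")) +
    ggplot2::labs(x = "expression rank", y = "share of gene expression",
                  fill = "channel-forming") +
    ggplot2::theme_minimal()
}
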