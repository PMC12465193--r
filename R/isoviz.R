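# Aligned isoform-structure visualization: a stack of exon rows on a
# shared x-axis where exon widths are proportional to exon length but
# intron widths are a fixed constant, with ORF and protein-domain
# overlays.

#' Exons preserved across all chosen variants
#'
#' @param variants A `splice_catalog` tibble.
#' @param universe Optional `exon_universe`; built from `variants` when
#'   absent.
#' @return Integer vector of exon numbers present in every variant.
#' @export
preserved_exons <- function(variants, universe = NULL) {
  if (is.null(universe)) universe <- build_universe(variants)
  sets <- split(universe$membership$exon_number,
                universe$membership$variant_id)
  sets <- sets[variants$variant_id]
  Reduce(intersect, sets)
}

#' Plan an aligned exon-stack layout
#'
#' Computes display coordinates for a stack of variant rows: the exon
#' universe of the chosen variants defines shared x-slots (exon display
#' width proportional to exon length in nt, intron display width a fixed
#' constant regardless of genomic length), so identical genomic exons
#' align exactly across rows. Each block is annotated with whether it
#' overlaps the variant's ORF and with any domain whose protein
#' coordinates, mapped through the ORF (nt = orf_start + (aa-1)*3 ..
#' orf_start + aa*3, partial-codon overlaps included), intersect the
#' exon. Rows are labeled with read counts.
#'
#' @param variants A `splice_catalog` tibble (the row order is the
#'   display order, top to bottom).
#' @param orfs Tibble from [find_orfs()] (may be empty).
#' @param hits Domain-hit tibble (may be empty).
#' @param expression Optional tibble `variant_id`, `count` (or long
#'   counts, pooled automatically) used for row labels; ids present here
#'   but absent from `variants` are skipped with a warning.
#' @param intron_width Display width of every intron gap (default 12).
#' @param nt_per_unit Exon nt per display unit (default 10).
#' @return An `isoviz_plan`: list with `blocks` (tibble `variant_id`,
#'   `exon_number`, `x0`, `x1`, `y`, `in_orf`, `domain`, `preserved`),
#'   `rows` (tibble `variant_id`, `y`, `label`), `slots`, `intron_width`.
#' @export
plan_layout <- function(variants, orfs, hits, expression = NULL,
                        intron_width = 12, nt_per_unit = 10) {
  if (is.null(orfs) || !"variant_id" %in% names(orfs)) {
    orfs <- tibble::tibble(variant_id = character(), start_nt = integer(),
                           end_nt = integer())
  }
  if (is.null(hits) || !"variant_id" %in% names(hits)) {
    hits <- tibble::tibble(variant_id = character(), accession = character(),
                           aa_from = integer(), aa_to = integer())
  }
  universe <- build_universe(variants)
  ex <- universe$exons |> dplyr::arrange(.data$exon_number)
  widths <- (ex$end - ex$start) / nt_per_unit
  x1 <- cumsum(widths + intron_width) - intron_width
  slots <- ex |>
    dplyr::mutate(x0 = x1 - widths, x1 = x1)
  kept <- preserved_exons(variants, universe)

  if (!is.null(expression)) {
    if ("count" %in% names(expression) && "sample_id" %in% names(expression)) {
      expression <- expression |>
        dplyr::group_by(.data$variant_id) |>
        dplyr::summarise(count = sum(.data$count), .groups = "drop")
    }
    extra <- setdiff(expression$variant_id, variants$variant_id)
    if (length(extra) > 0) {
      warning("expression rows without structures skipped: ",
              paste(utils::head(extra, 3), collapse = ", "), call. = FALSE)
    }
  }

  mem <- universe$membership
  exon_len <- stats::setNames(ex$end - ex$start, ex$exon_number)
  block_rows <- purrr::map(seq_len(nrow(variants)), function(i) {
    v <- variants$variant_id[i]
    m <- mem[mem$variant_id == v, ]
    m <- m[order(m$position), ]
    lens <- exon_len[as.character(m$exon_number)]
    tx0 <- cumsum(c(0L, lens[-length(lens)]))  # transcript offset per exon
    orf <- orfs[orfs$variant_id == v, ]
    vhits <- hits[hits$variant_id == v, ]
    in_orf <- rep(FALSE, nrow(m))
    domain <- rep(NA_character_, nrow(m))
    if (nrow(orf) == 1) {
      in_orf <- tx0 < orf$end_nt & (tx0 + lens) > orf$start_nt
      if (nrow(vhits) > 0) {
        d_nt0 <- orf$start_nt + (vhits$aa_from - 1L) * 3L
        d_nt1 <- orf$start_nt + vhits$aa_to * 3L
        for (b in seq_len(nrow(m))) {
          ov <- which(d_nt0 < tx0[b] + lens[b] & d_nt1 > tx0[b])
          if (length(ov) > 0) {
            domain[b] <- paste(sort(unique(vhits$accession[ov])),
                               collapse = ",")
          }
        }
      }
    }
    tibble::tibble(
      variant_id = v, exon_number = m$exon_number,
      x0 = slots$x0[match(m$exon_number, slots$exon_number)],
      x1 = slots$x1[match(m$exon_number, slots$exon_number)],
      y = i, in_orf = in_orf, domain = domain,
      preserved = m$exon_number %in% kept)
  })
  labels <- variants$variant_id
  if (!is.null(expression)) {
    cnt <- expression$count[match(variants$variant_id,
                                  expression$variant_id)]
    labels <- ifelse(is.na(cnt), labels,
                     sprintf("%s (%s reads)", labels,
                             format(cnt, big.mark = ",", trim = TRUE)))
  }
  structure(list(
    blocks = dplyr::bind_rows(block_rows),
    rows = tibble::tibble(variant_id = variants$variant_id,
                          y = seq_len(nrow(variants)), label = labels),
    slots = slots, intron_width = intron_width
  ), class = "isoviz_plan")
}

#' @export
print.isoviz_plan <- function(x, ...) {
  cat(sprintf("<isoviz_plan> %d variants x %d exon slots\n",
              nrow(x$rows), nrow(x$slots)))
  invisible(x)
}

default_domain_colors <- function() {
  c(pfam00520 = "#d62728",  # pore-forming (Ion_trans): red
    pfam16905 = "#1f77b4",  # GPHH: blue
    pfam08763 = "#9467bd",  # IQ: purple
    orf = "#bfbfbf", none = "#ffffff")
}

block_fill <- function(blocks, colors) {
  fill <- rep(colors[["none"]], nrow(blocks))
  fill[blocks$in_orf] <- colors[["orf"]]
  for (acc in c("pfam00520", "pfam16905", "pfam08763")) {
    hit <- !is.na(blocks$domain) &
      vapply(strsplit(blocks$domain, ","), function(d) acc %in% d,
             logical(1))
    fill[hit] <- colors[[acc]]
  }
  fill
}

#' Render a layout plan as a deterministic SVG file
#'
#' Identical plans produce byte-identical SVG output. Pore-forming, GPHH
#' and IQ domains are drawn in distinct configurable colors; rows carry
#' their labels.
#'
#' @param plan An `isoviz_plan`.
#' @param path Output path (`.svg`).
#' @param colors Named fill colors (see `default_domain_colors`).
#' @param row_height,row_gap Geometry in display units.
#' @return `path`, invisibly.
#' @export
render_svg <- function(plan, path, colors = default_domain_colors(),
                       row_height = 14, row_gap = 8) {
  if (nrow(plan$rows) == 0 || nrow(plan$blocks) == 0) {
    stop("empty layout plan", call. = FALSE)
  }
  label_pad <- 220
  width <- ceiling(max(plan$blocks$x1) + label_pad + 20)
  height <- nrow(plan$rows) * (row_height + row_gap) + row_gap
  y_of <- function(y) row_gap + (y - 1) * (row_height + row_gap)
  fill <- block_fill(plan$blocks, colors)

  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height),
    '<style>text { font-family: monospace; font-size: 10px; }</style>',
    # per-row baseline connecting first to last block
    vapply(seq_len(nrow(plan$rows)), function(i) {
      b <- plan$blocks[plan$blocks$y == plan$rows$y[i], ]
      sprintf('<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="#888888" stroke-width="1"/>',
              min(b$x0) + 10, y_of(plan$rows$y[i]) + row_height / 2,
              max(b$x1) + 10, y_of(plan$rows$y[i]) + row_height / 2)
    }, ""),
    vapply(seq_len(nrow(plan$blocks)), function(i) {
      b <- plan$blocks[i, ]
      sprintf('<rect x="%.2f" y="%.2f" width="%.2f" height="%d" fill="%s" stroke="#333333" stroke-width="0.5"/>',
              b$x0 + 10, y_of(b$y), b$x1 - b$x0, row_height, fill[i])
    }, ""),
    vapply(seq_len(nrow(plan$rows)), function(i) {
      sprintf('<text x="%.2f" y="%.2f">%s</text>',
              max(plan$blocks$x1) + 20, y_of(plan$rows$y[i]) + row_height - 3,
              plan$rows$label[i])
    }, ""),
    '</svg>'
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' ggplot2 view of a layout plan
#'
#' @param object An `isoviz_plan`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.isoviz_plan <- function(object, ...) {
  colors <- default_domain_colors()
  blocks <- object$blocks |>
    dplyr::mutate(fill_key = dplyr::case_when(
      !is.na(.data$domain) & grepl("pfam00520", .data$domain) ~ "pore (pfam00520)",
      !is.na(.data$domain) & grepl("pfam16905", .data$domain) ~ "GPHH (pfam16905)",
      !is.na(.data$domain) & grepl("pfam08763", .data$domain) ~ "IQ (pfam08763)",
      .data$in_orf ~ "ORF",
      TRUE ~ "non-coding"))
  ggplot2::ggplot(blocks) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$x0, xmax = .data$x1,
                                    ymin = -.data$y - 0.4,
                                    ymax = -.data$y + 0.4,
                                    fill = .data$fill_key),
                       color = "grey20", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(
      "pore (pfam00520)" = colors[["pfam00520"]],
      "GPHH (pfam16905)" = colors[["pfam16905"]],
      "IQ (pfam08763)" = colors[["pfam08763"]],
      "ORF" = colors[["orf"]], "non-coding" = colors[["none"]])) +
    ggplot2::scale_y_continuous(breaks = -object$rows$y,
                                labels = object$rows$label) +
    ggplot2::labs(x = "display coordinate (introns fixed-width)", y = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}
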