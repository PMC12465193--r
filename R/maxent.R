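# Maximum-entropy splice-site scoring: donor sites are 9-mers with GT at
# 1-based positions 4-5 (3 exonic bases, GT, 6 intronic bases); acceptor
# sites are 23-mers with AG at positions 19-20 (18 upstream, AG, 3
# downstream). A model supplies P_me and P_null for every k-mer; the
# score is log2(P_me / P_null).

DONOR_LEN <- 9L
ACCEPTOR_LEN <- 23L

#' Construct a maximum-entropy splice-site model
#'
#' Each of the four components (`donor_me`, `donor_null`, `acceptor_me`,
#' `acceptor_null`) is either a position x base probability matrix
#' (columns `A`, `C`, `G`, `T`; k-mer probability = product over
#' positions) or a named numeric vector of explicit per-k-mer
#' probabilities. All probabilities must lie in (0, 1].
#'
#' @param donor_me,donor_null Donor (9-mer) foreground/background.
#' @param acceptor_me,acceptor_null Acceptor (23-mer)
#'   foreground/background.
#' @param provenance Free-text label of where the tables came from.
#' @return A `maxent_model`.
#' @export
maxent_model <- function(donor_me, donor_null, acceptor_me, acceptor_null,
                         provenance = "unspecified") {
  check_component <- function(x, k, what) {
    if (is.matrix(x)) {
      if (nrow(x) != k || !all(c("A", "C", "G", "T") %in% colnames(x))) {
        stop(sprintf("%s: need a %d x 4 matrix with A,C,G,T columns", what, k),
             call. = FALSE)
      }
      vals <- x[, c("A", "C", "G", "T")]
    } else if (is.numeric(x) && !is.null(names(x))) {
      if (any(nchar(names(x)) != k)) {
        stop(sprintf("%s: k-mer names must have length %d", what, k),
             call. = FALSE)
      }
      vals <- x
    } else {
      stop(what, ": must be a probability matrix or named k-mer vector",
           call. = FALSE)
    }
    if (any(vals <= 0 | vals > 1)) {
      stop(what, ": probabilities must lie in (0, 1]", call. = FALSE)
    }
    x
  }
  structure(list(
    donor = list(me = check_component(donor_me, DONOR_LEN, "donor_me"),
                 null = check_component(donor_null, DONOR_LEN, "donor_null")),
    acceptor = list(me = check_component(acceptor_me, ACCEPTOR_LEN, "acceptor_me"),
                    null = check_component(acceptor_null, ACCEPTOR_LEN, "acceptor_null")),
    provenance = provenance
  ), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> provenance: %s\n", x$provenance))
  invisible(x)
}

#' A flat synthetic model scoring every site 0
#'
#' Foreground equals background (uniform positional probabilities), so
#' every k-mer scores exactly 0 bits. Useful as a test baseline.
#'
#' @return A `maxent_model`.
#' @export
uniform_maxent_model <- function() {
  mk <- function(k) {
    m <- matrix(0.25, nrow = k, ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
    m
  }
  maxent_model(mk(DONOR_LEN), mk(DONOR_LEN), mk(ACCEPTOR_LEN),
               mk(ACCEPTOR_LEN), provenance = "uniform synthetic")
}

#' Read positional maximum-entropy tables from a directory
#'
#' Expects four whitespace-separated files — `donor_me.tsv`,
#' `donor_null.tsv`, `acceptor_me.tsv`, `acceptor_null.tsv` — each with a
#' header `pos A C G T` and one row per k-mer position.
#'
#' @param dir Directory holding the four tables.
#' @return A `maxent_model`.
#' @export
read_maxent_tables <- function(dir) {
  load_one <- function(name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    if (!file.exists(path)) stop("missing model table: ", path, call. = FALSE)
    tab <- utils::read.table(path, header = TRUE)
    m <- as.matrix(tab[, c("A", "C", "G", "T")])
    rownames(m) <- NULL
    m
  }
  maxent_model(load_one("donor_me"), load_one("donor_null"),
               load_one("acceptor_me"), load_one("acceptor_null"),
               provenance = dir)
}

#' Write a positional model's tables to a directory
#'
#' @param model A `maxent_model` with matrix components.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_maxent_tables <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dump_one <- function(m, name) {
    if (!is.matrix(m)) stop("only matrix components can be written",
                            call. = FALSE)
    df <- data.frame(pos = seq_len(nrow(m)), m[, c("A", "C", "G", "T")])
    utils::write.table(df, file.path(dir, paste0(name, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  dump_one(model$donor$me, "donor_me")
  dump_one(model$donor$null, "donor_null")
  dump_one(model$acceptor$me, "acceptor_me")
  dump_one(model$acceptor$null, "acceptor_null")
  invisible(dir)
}

kmer_prob <- function(component, kmer) {
  if (is.matrix(component)) {
    bases <- strsplit(kmer, "")[[1]]
    prod(component[cbind(seq_along(bases), match(bases, colnames(component)))])
  } else {
    p <- component[[kmer]]
    if (is.null(p) || is.na(p)) {
      stop("k-mer absent from explicit model table: ", kmer, call. = FALSE)
    }
    p
  }
}

#' Score one splice-site k-mer
#'
#' @param kmer 9-mer (donor) or 23-mer (acceptor) over `{A,C,G,T}`.
#' @param model A `maxent_model`.
#' @param site_type `"donor"` or `"acceptor"`.
#' @return `log2(P_me(kmer) / P_null(kmer))`.
#' @export
score_site <- function(kmer, model, site_type = c("donor", "acceptor")) {
  site_type <- match.arg(site_type)
  if (grepl("N", kmer, fixed = TRUE)) {
    stop("undefined score: k-mer contains N", call. = FALSE)
  }
  expected <- if (site_type == "donor") DONOR_LEN else ACCEPTOR_LEN
  if (nchar(kmer) != expected) {
    stop(sprintf("%s k-mer must have length %d", site_type, expected),
         call. = FALSE)
  }
  comp <- model[[site_type]]
  log2(kmer_prob(comp$me, kmer) / kmer_prob(comp$null, kmer))
}

#' Find candidate donor and acceptor splice sites in a sequence
#'
#' Every `GT` with >= 3 bases upstream and >= 4 downstream yields a donor
#' 9-mer; every `AG` with >= 18 bases upstream and >= 3 downstream yields
#' an acceptor 23-mer. K-mers containing `N` are skipped and counted in
#' the `n_skipped` attribute.
#'
#' @param sequence Sequence over `{A,C,G,T,N}`.
#' @return Tibble `position` (0-based offset of the G of GT / A of AG),
#'   `site_type`, `kmer`; attribute `n_skipped`.
#' @export
find_sites <- function(sequence) {
  s <- toupper(sequence)
  n <- nchar(s)
  grab <- function(motif, up, k) {
    hits <- gregexpr(motif, s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(integer())
    hits <- as.integer(hits)  # 1-based position of first motif base
    hits[hits - up >= 1L & hits - up + k - 1L <= n]
  }
  d <- grab("GT", 3L, DONOR_LEN)
  a <- grab("AG", 18L, ACCEPTOR_LEN)
  window_tbl <- function(hits, up, k, type) {
    if (length(hits) == 0L) {
      return(tibble::tibble(position = integer(), site_type = character(),
                            kmer = character()))
    }
    tibble::tibble(position = hits - 1L, site_type = type,
                   kmer = substring(s, hits - up, hits - up + k - 1L))
  }
  out <- dplyr::bind_rows(
    window_tbl(d, 3L, DONOR_LEN, "donor"),
    window_tbl(a, 18L, ACCEPTOR_LEN, "acceptor")
  )
  skip <- grepl("N", out$kmer, fixed = TRUE)
  res <- out[!skip, ] |> dplyr::arrange(.data$position, .data$site_type)
  attr(res, "n_skipped") <- sum(skip)
  res
}

#' Scan and score every splice site in a sequence catalog
#'
#' @param sequences Named character vector (sequence_id -> sequence).
#' @param model A `maxent_model`.
#' @return Tibble `sequence_id`, `position`, `site_type`, `kmer`, `score`,
#'   ordered by sequence id then position; attribute `medians` holds the
#'   per-site-type median scores (`NA` when a type has no sites).
#' @export
scan_catalog <- function(sequences, model) {
  rows <- purrr::imap(sequences, function(s, id) {
    sites <- find_sites(s)
    if (nrow(sites) == 0) return(NULL)
    sites$score <- vapply(seq_len(nrow(sites)), function(i)
      score_site(sites$kmer[i], model, sites$site_type[i]), numeric(1))
    dplyr::mutate(sites, sequence_id = id, .before = 1)
  }) |>
    dplyr::bind_rows()
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(sequence_id = character(), position = integer(),
                           site_type = character(), kmer = character(),
                           score = double())
    warning("empty catalog: no splice sites found; medians undefined",
            call. = FALSE)
  }
  rows <- dplyr::arrange(rows, .data$sequence_id, .data$position)
  attr(rows, "medians") <- c(
    donor = stats::median(rows$score[rows$site_type == "donor"]),
    acceptor = stats::median(rows$score[rows$site_type == "acceptor"]))
  rows
}
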