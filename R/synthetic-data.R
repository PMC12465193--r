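# Synthetic multi-exon gene, isoform truth set, noisy long reads and
# conservation tracks with known ground truth. The generator emulates a
# targeted amplicon over a large voltage-gated calcium-channel-like gene:
# a ~50-exon locus, a handful of true isoforms differing by skipped
# internal exons, long reads corrupted by junction wobble, exon skipping
# and terminal truncation, and a noise-free short-read junction table used
# as the correction reference.

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                    c("T", "C", "A", "G")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

# Marker peptides planted in designated exons so that a domain table with
# consistent protein coordinates can be generated for any isoform.
MARKER_PEPTIDES <- list(
  pore = list(peptide = "DEWWHEWWDE", accession = "pfam00520", name = "Ion_trans"),
  gphh = list(peptide = "HHGGHHGGHH", accession = "pfam16905", name = "GPHH"),
  iq   = list(peptide = "IQWIQWIQWI", accession = "pfam08763", name = "Ca_chan_IQ")
)

codons_for <- function(peptide) {
  lut <- Biostrings::GENETIC_CODE
  vapply(strsplit(peptide, "")[[1]],
         function(aa) names(lut)[lut == aa][1], "")
}

#' Generate a synthetic multi-exon gene model
#'
#' Builds a deterministic (per seed) gene locus: `n_exons` exons with
#' lengths drawn from 60-300 nt (multiples of 3, so any exon subset keeps
#' the reading frame), introns 100-5000 nt with canonical `GT..AG`
#' boundaries, and a genome sequence whose exons concatenate into a
#' stop-free open reading frame starting with `ATG` and ending with a stop
#' codon. Four spread-out exons carry an in-frame pore-domain marker
#' peptide; the two exons before the last carry calmodulin-regulation
#' (GPHH/IQ) markers, so domain tables can be generated consistently for
#' any isoform.
#'
#' @param n_exons Number of exons (>= 3).
#' @param seed Integer seed; the same seed reproduces the model exactly.
#' @param exon_len_range,intron_len_range Length ranges in nt.
#' @param strand `"+"` or `"-"`.
#' @return A `gene_model`: list with `chrom`, `strand`, `exons` (tibble
#'   `exon`, `start`, `end`), `seq` (locus sequence), `chrom_len`,
#'   `pore_exons`, `gphh_exon`, `iq_exon`.
#' @export
make_gene <- function(n_exons, seed, exon_len_range = c(60, 300),
                      intron_len_range = c(100, 5000), strand = "+") {
  if (n_exons < 3) stop("n_exons must be >= 3", call. = FALSE)
  set.seed(seed)
  lens <- sample(seq(exon_len_range[1] - exon_len_range[1] %% 3,
                     exon_len_range[2], by = 3L), n_exons, replace = TRUE)
  introns <- sample(seq(intron_len_range[1], intron_len_range[2]),
                    n_exons - 1L, replace = TRUE)
  starts <- 1000L + cumsum(c(0L, lens[-n_exons] + introns))
  exons <- tibble::tibble(exon = seq_len(n_exons), start = starts,
                          end = starts + lens)
  chrom_len <- max(exons$end) + 1000L

  # exonic sequence: one stop-free ORF in transcription order
  n_codons <- sum(lens) %/% 3L
  codons <- sample(SENSE_CODONS, n_codons, replace = TRUE)
  codons[1] <- "ATG"
  codons[n_codons] <- "TAA"
  # plant marker peptides at codon offset 2 of designated exons
  pore_exons <- unique(round(seq(2, n_exons - 2, length.out = 4)))
  gphh_exon <- n_exons - 1L
  iq_exon <- n_exons
  codon_offsets <- cumsum(c(0L, lens %/% 3L))
  plant <- function(codons, exon_idx, peptide) {
    at <- codon_offsets[exon_idx] + 2L
    cd <- codons_for(peptide)
    codons[at:(at + length(cd) - 1L)] <- cd
    codons
  }
  for (e in pore_exons) codons <- plant(codons, e, MARKER_PEPTIDES$pore$peptide)
  codons <- plant(codons, gphh_exon, MARKER_PEPTIDES$gphh$peptide)
  codons <- plant(codons, iq_exon, MARKER_PEPTIDES$iq$peptide)
  exonic <- paste(codons, collapse = "")

  genome <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  # in transcription order the i-th exon carries exonic[cum] slices
  tx_order <- if (strand == "+") seq_len(n_exons) else rev(seq_len(n_exons))
  pos <- 1L
  for (i in tx_order) {
    sub <- substr(exonic, pos, pos + lens[i] - 1L)
    piece <- strsplit(if (strand == "+") sub else reverse_complement(sub), "")[[1]]
    genome[(exons$start[i] + 1L):exons$end[i]] <- piece
    pos <- pos + lens[i]
  }
  # canonical splice motifs at every intron boundary (genomic orientation)
  for (i in seq_len(n_exons - 1L)) {
    d <- exons$end[i]; a <- exons$start[i + 1L]
    if (strand == "+") {
      genome[c(d + 1L, d + 2L)] <- c("G", "T")
      genome[c(a - 1L, a)] <- c("A", "G")
    } else {
      genome[c(d + 1L, d + 2L)] <- c("C", "T")
      genome[c(a - 1L, a)] <- c("A", "C")
    }
  }
  structure(list(
    chrom = "chrS", strand = strand, exons = exons,
    seq = paste(genome, collapse = ""), chrom_len = chrom_len,
    pore_exons = pore_exons, gphh_exon = gphh_exon, iq_exon = iq_exon
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s(%s): %d exons over %d bp\n", x$chrom,
              x$strand, nrow(x$exons), max(x$exons$end) - min(x$exons$start)))
  invisible(x)
}

#' Spliced transcript sequence of an exon-index chain
#'
#' @param model A `gene_model`.
#' @param exon_idx Integer exon indices (genomic numbering of the model).
#' @return Transcript sequence in transcription orientation (minus-strand
#'   models are reverse-complemented).
#' @export
transcript_seq <- function(model, exon_idx) {
  exon_idx <- sort(exon_idx)
  pieces <- substring(model$seq, model$exons$start[exon_idx] + 1L,
                      model$exons$end[exon_idx])
  s <- paste(pieces, collapse = "")
  if (model$strand == "-") reverse_complement(s) else s
}

#' Define a ground-truth isoform set and abundances
#'
#' Isoform 1 is the full exon chain; each further isoform skips a distinct
#' small set of internal exons (never the pore-marker exons unless
#' `cassette_exons` is given, in which case exactly those exons are skipped
#' one per isoform, yielding a catalog whose only alternative structure is
#' those cassette exons). Per-sample abundances are drawn uniformly from
#' `abundance_range`.
#'
#' @param model A `gene_model`.
#' @param n_isoforms Number of true isoforms (>= 1).
#' @param samples Sample ids.
#' @param seed Integer seed.
#' @param cassette_exons Optional exon indices to plant as clean cassette
#'   events (one skipped exon per extra isoform; overrides `n_isoforms`).
#' @param abundance_range Per-sample read-count range per isoform.
#' @param wobble_prob,wobble_max Junction-endpoint corruption: an endpoint
#'   moves with probability `wobble_prob`, by a uniform offset in
#'   `[-wobble_max, -1] U [1, wobble_max]`.
#' @param skip_prob Per-internal-exon skip probability per read.
#' @param trunc_prob Per-end truncation probability per read.
#' @return A `synthetic_truth` list.
#' @export
make_truth <- function(model, n_isoforms = 6,
                       samples = c("G10", "G90", "N10", "N90"), seed = 1,
                       cassette_exons = NULL,
                       abundance_range = c(30, 1000),
                       wobble_prob = 0.3, wobble_max = 8,
                       skip_prob = 0, trunc_prob = 0) {
  set.seed(seed + 1L)
  n_exons <- nrow(model$exons)
  all_idx <- seq_len(n_exons)
  if (!is.null(cassette_exons)) {
    stopifnot(all(cassette_exons > 1 & cassette_exons < n_exons))
    isoforms <- c(list(all_idx),
                  lapply(cassette_exons, function(e) setdiff(all_idx, e)))
  } else {
    protected <- c(1L, n_exons, model$pore_exons)
    skippable <- setdiff(all_idx, protected)
    isoforms <- list(all_idx)
    seen <- character()
    while (length(isoforms) < n_isoforms) {
      k <- min(sample(1:2, 1), length(skippable))
      drop <- sort(skippable[sample.int(length(skippable), k)])
      key <- paste(drop, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      isoforms <- c(isoforms, list(setdiff(all_idx, drop)))
    }
  }
  names(isoforms) <- sprintf("iso%02d", seq_along(isoforms))
  # isoform expression is heavy-tailed (a dominant isoform plus minor
  # ones spanning decades): base abundances sit on a jittered geometric
  # ladder over the range, so consecutive isoforms differ by a constant
  # log step and the truth ranking stays identifiable against sampling
  # noise at the simulated depth
  n_iso <- length(isoforms)
  ladder <- exp(seq(log(abundance_range[1]), log(abundance_range[2]),
                    length.out = max(n_iso, 2L)))[seq_len(n_iso)]
  base <- round(ladder * stats::runif(n_iso, 0.9, 1.1))
  base <- base[sample.int(n_iso)]
  abundance <- tidyr::expand_grid(isoform_id = names(isoforms),
                                  sample_id = samples) |>
    dplyr::mutate(abundance = pmax(1L, as.integer(round(
      base[match(.data$isoform_id, names(isoforms))] *
        stats::runif(dplyr::n(), 0.7, 1.3)))))
  structure(list(
    isoforms = isoforms, abundance = abundance, samples = samples,
    wobble_prob = wobble_prob, wobble_max = wobble_max,
    skip_prob = skip_prob, trunc_prob = trunc_prob, seed = seed
  ), class = "synthetic_truth")
}

isoform_blocks <- function(model, exon_idx) {
  tibble::tibble(start = model$exons$start[exon_idx],
                 end = model$exons$end[exon_idx])
}

#' Simulate noisy long reads and the short-read junction table
#'
#' Each read is drawn from a true isoform in proportion to its per-sample
#' abundance, then corrupted in order: terminal truncation (whole terminal
#' exons removed plus a partial trim of the new terminal block), random
#' internal-exon skipping, and junction wobble (independent integer offsets
#' of donor/acceptor endpoints). The returned junction table holds the
#' *uncorrupted* junction observations (post-truncation, pre-skip/wobble),
#' mirroring the use of short-read junctions as a noise-free correction
#' reference.
#'
#' @param model A `gene_model`.
#' @param truth A `synthetic_truth` from [make_truth()].
#' @param n_reads Optional named vector of reads per sample; default is
#'   each sample's total truth abundance (so expected reads per isoform
#'   equal the truth abundances).
#' @param seed Integer seed.
#' @return List with `reads` (block-level tibble), `junctions` (support
#'   table), `assignments` (read_id, sample_id, isoform_id), and `seed`.
#' @export
simulate_reads <- function(model, truth, n_reads = NULL, seed = truth$seed) {
  set.seed(seed + 2L)
  ab <- truth$abundance
  samples <- truth$samples
  if (is.null(n_reads)) {
    n_reads <- vapply(samples, function(s)
      sum(ab$abundance[ab$sample_id == s]), numeric(1))
  }
  if (any(n_reads <= 0)) stop("n_reads must be positive", call. = FALSE)

  total <- sum(unlist(n_reads))
  starts_l <- vector("list", total); ends_l <- vector("list", total)
  rid_v <- character(total); smp_v <- character(total); iso_v <- character(total)
  junc_d <- vector("list", total); junc_a <- vector("list", total)
  wob <- c(-(1:truth$wobble_max), 1:truth$wobble_max)
  counter <- 0L
  for (s in samples) {
    w <- ab |> dplyr::filter(.data$sample_id == s)
    w <- w$abundance[match(names(truth$isoforms), w$isoform_id)]
    draws <- sample(names(truth$isoforms), n_reads[[s]], replace = TRUE,
                    prob = w)
    for (iso in draws) {
      counter <- counter + 1L
      chain <- truth$isoforms[[iso]]
      bs <- model$exons$start[chain]; be <- model$exons$end[chain]

      # truncation: drop whole terminal exons + partial trim (per end)
      for (end3 in c(FALSE, TRUE)) {
        if (length(bs) > 2L && stats::runif(1) < truth$trunc_prob) {
          n_drop <- sample.int(max(1L, length(bs) %/% 3L), 1)
          keep <- if (end3) seq_len(length(bs) - n_drop)
                  else (n_drop + 1L):length(bs)
          bs <- bs[keep]; be <- be[keep]
          i <- if (end3) length(bs) else 1L
          trim <- sample.int(be[i] - bs[i] - 20L, 1) - 1L
          if (end3) be[i] <- be[i] - trim else bs[i] <- bs[i] + trim
        }
      }
      # record uncorrupted junction observations
      k <- length(bs) - 1L
      if (k > 0L) {
        junc_d[[counter]] <- be[-(k + 1L)]
        junc_a[[counter]] <- bs[-1L]
      }
      # exon skipping (internal blocks only)
      if (length(bs) > 2L && truth$skip_prob > 0) {
        internal <- 2:(length(bs) - 1L)
        drop <- internal[stats::runif(length(internal)) < truth$skip_prob]
        if (length(drop) > 0) { bs <- bs[-drop]; be <- be[-drop] }
      }
      # junction wobble: donors first, then acceptors against updated donors
      k <- length(bs) - 1L
      if (k > 0L && truth$wobble_prob > 0) {
        move <- stats::runif(k) < truth$wobble_prob
        if (any(move)) {
          newd <- be[seq_len(k)] + ifelse(move, sample(wob, k, TRUE), 0L)
          ok <- newd > bs[seq_len(k)] + 1L & newd < bs[seq_len(k) + 1L]
          be[seq_len(k)][move & ok] <- newd[move & ok]
        }
        move <- stats::runif(k) < truth$wobble_prob
        if (any(move)) {
          newa <- bs[seq_len(k) + 1L] + ifelse(move, sample(wob, k, TRUE), 0L)
          ok <- newa > be[seq_len(k)] & newa < be[seq_len(k) + 1L] - 1L
          bs[seq_len(k) + 1L][move & ok] <- newa[move & ok]
        }
      }
      starts_l[[counter]] <- bs; ends_l[[counter]] <- be
      rid_v[counter] <- sprintf("r%06d", counter)
      smp_v[counter] <- s; iso_v[counter] <- iso
    }
  }
  n_blocks <- lengths(starts_l)
  reads <- tibble::tibble(
    read_id = rep(rid_v, n_blocks), sample_id = rep(smp_v, n_blocks),
    chrom = model$chrom, strand = model$strand,
    start = as.integer(unlist(starts_l)), end = as.integer(unlist(ends_l)),
    block = unlist(lapply(n_blocks, seq_len)))
  junctions <- tibble::tibble(donor = as.integer(unlist(junc_d)),
                              acceptor = as.integer(unlist(junc_a))) |>
    dplyr::count(.data$donor, .data$acceptor, name = "support") |>
    dplyr::mutate(chrom = model$chrom, strand = model$strand) |>
    dplyr::select("chrom", "donor", "acceptor", "strand", "support") |>
    dplyr::arrange(.data$donor)
  list(reads = reads,
       junctions = junctions,
       assignments = tibble::tibble(read_id = rid_v, sample_id = smp_v,
                                    isoform_id = iso_v),
       seed = seed)
}

#' Synthetic basewise conservation track
#'
#' Per-base scores are drawn `Normal(exon_mean, noise_sd)` on exonic bases
#' and `Normal(intron_mean, noise_sd)` elsewhere, clipped to `range`, and
#' returned run-length encoded in bedGraph layout.
#'
#' @param model A `gene_model`.
#' @param exon_mean,intron_mean Mean score on exonic/intronic bases; the
#'   default exonic mean 1.3 matches the highly conserved regime of
#'   phyloP-like tracks.
#' @param noise_sd Per-base standard deviation.
#' @param seed Integer seed.
#' @param range Clipping range of the track.
#' @return Tibble `chrom`, `start`, `end`, `score` (0-based half-open).
#' @export
make_conservation_track <- function(model, exon_mean = 1.3, intron_mean = 0,
                                    noise_sd = 0.2, seed = 1,
                                    range = c(-20, 10)) {
  set.seed(seed + 3L)
  n <- model$chrom_len
  exonic <- logical(n)
  for (i in seq_len(nrow(model$exons))) {
    exonic[(model$exons$start[i] + 1L):model$exons$end[i]] <- TRUE
  }
  mu <- ifelse(exonic, exon_mean, intron_mean)
  score <- mu + (if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0)
  score <- pmin(pmax(score, range[1]), range[2])
  runs <- rle(score)
  ends <- cumsum(runs$lengths)
  tibble::tibble(chrom = model$chrom,
                 start = as.integer(ends - runs$lengths),
                 end = as.integer(ends),
                 score = runs$values)
}

#' Generate a CDD-style domain table by scanning proteins for the planted
#' marker peptides
#'
#' @param proteins Named character vector of protein sequences (typically
#'   `orfs$protein` named by `variant_id`).
#' @return Tibble `variant_id`, `accession`, `name`, `aa_from`, `aa_to`,
#'   `evalue`, one row per marker occurrence.
#' @export
scan_marker_domains <- function(proteins) {
  purrr::imap(MARKER_PEPTIDES, function(m, key) {
    hits <- purrr::imap(proteins, function(p, id) {
      at <- gregexpr(m$peptide, p, fixed = TRUE)[[1]]
      if (at[1] == -1L) return(NULL)
      tibble::tibble(variant_id = id, accession = m$accession, name = m$name,
                     aa_from = as.integer(at),
                     aa_to = as.integer(at) + nchar(m$peptide) - 1L,
                     evalue = 1e-30)
    })
    dplyr::bind_rows(hits)
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$variant_id, .data$aa_from)
}

#' Write a junction table in SJ dialect
#'
#' Writes 1-based inclusive intron coordinates with strand codes (1 = `+`,
#' 2 = `-`, 0 = undefined), readable by [read_junction_table()].
#'
#' @param junctions Tibble `chrom`, `donor`, `acceptor`, `strand`,
#'   `support` (internal 0-based half-open convention).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junction_table <- function(junctions, path) {
  code <- c("+" = 1L, "-" = 2L)[junctions$strand]
  code[is.na(code)] <- 0L
  readr::write_lines(sprintf("%s\t%d\t%d\t%d\t%d", junctions$chrom,
                             junctions$donor + 1L, junctions$acceptor,
                             code, junctions$support), path)
  invisible(path)
}

#' Write a full synthetic dataset to disk
#'
#' Emits BED12 reads, an SJ-style junction table, the locus FASTA, a
#' bedGraph conservation track and a truth JSON, so the file-based entry
#' points of the pipeline can be exercised end to end.
#'
#' @param model,truth,sim Objects from [make_gene()], [make_truth()],
#'   [simulate_reads()].
#' @param dir Output directory (created if needed).
#' @param track Optional conservation track tibble.
#' @return Named list of written paths, invisibly.
#' @export
write_synthetic_dataset <- function(model, truth, sim, dir, track = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    reads = file.path(dir, "reads.bed"),
    junctions = file.path(dir, "junctions.sj.tab"),
    genome = file.path(dir, "genome.fa"),
    truth = file.path(dir, "truth.json")
  )
  write_bed12(sim$reads, paths$reads)
  write_junction_table(sim$junctions, paths$junctions)
  write_fasta(stats::setNames(model$seq, model$chrom), paths$genome)
  if (!is.null(track)) {
    paths$conservation <- file.path(dir, "conservation.bedGraph")
    write_conservation_bedgraph(track, paths$conservation)
  }
  jsonlite::write_json(list(
    isoforms = truth$isoforms, abundance = truth$abundance,
    noise = list(wobble_prob = truth$wobble_prob,
                 wobble_max = truth$wobble_max,
                 skip_prob = truth$skip_prob,
                 trunc_prob = truth$trunc_prob),
    seed = truth$seed
  ), paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
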