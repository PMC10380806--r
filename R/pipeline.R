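## End-to-end novel-MIRNA discovery: mapping, cluster calling,
## known-locus subtraction, hairpin/duplex evaluation, and
## processing-precision filtering across libraries.

#' Discover novel MIRNA loci across a set of libraries
#'
#' Maps each library to the genome, calls candidate loci on the pooled
#' alignments, removes candidates overlapping known MIRNA annotations,
#' folds each candidate's precursor window, derives the miRNA* of the
#' most abundant read, applies the duplex criteria, computes the
#' processing-precision ratio per library, and accepts candidates
#' passing all criteria in at least `min_libraries` libraries.
#'
#' @param genome a `Genome`.
#' @param libraries list of `ReadLibrary`.
#' @param known data.frame of known MIRNA intervals (or `NULL`).
#' @param min_reads,max_gap cluster-calling parameters.
#' @param min_libraries per-library pass count required to accept.
#' @param pad nt of genomic context added around a cluster before
#'   folding.
#' @param max_hairpin longest precursor window folded (clusters wider
#'   than this are trimmed around the candidate mature).
#' @param stranded restrict known-locus overlap to the same strand.
#' @param verbose print progress.
#' @return list with `accepted` (list of `MirnaLocus`), `summary`
#'   (per-candidate data.frame), `reports` (precision rows), and
#'   `candidates`.
#' @export
discover_novel_mirnas <- function(genome, libraries, known = NULL,
                                  min_reads = 10L, max_gap = 75L,
                                  min_libraries = 4L, pad = 10L,
                                  max_hairpin = 200L,
                                  stranded = FALSE, verbose = FALSE) {
  all_lens <- sort(unique(unlist(lapply(libraries, function(lib)
    nchar(lib$unique_reads$seq)))))
  all_lens <- all_lens[all_lens >= 18 & all_lens <= 30]
  idx <- genome_index(genome, all_lens)
  aln <- lapply(libraries, function(lib) {
    if (verbose) message("mapping ", lib$library_id)
    map_reads(genome, lib, index = idx)
  })
  names(aln) <- vapply(libraries, `[[`, character(1), "library_id")
  pooled <- do.call(rbind, aln)
  cands <- call_clusters(pooled, min_reads = min_reads, max_gap = max_gap)
  part <- intersect_known(cands, known, stranded = stranded)
  novel <- part$novel
  accepted <- list()
  reports <- list()
  summ <- list()
  for (ci in seq_along(novel)) {
    cand <- novel[[ci]]
    ev <- evaluate_candidate(cand, genome, libraries, aln,
                             pad = pad, max_hairpin = max_hairpin)
    nm <- sprintf("cand_%03d", ci)
    if (!is.null(ev$reports)) {
      ev$reports$locus <- nm
      reports[[nm]] <- ev$reports
    }
    filt <- if (is.null(ev$reports)) NULL else
      apply_mirna_filters(ev$reports, setNames(ev$duplex_passes, nm),
                          min_libraries = min_libraries)
    ok <- !is.null(filt) && filt$accepted
    summ[[nm]] <- data.frame(
      locus = nm, chrom = cand$chrom, start = cand$start,
      end = cand$end, strand = cand$strand,
      total_count = cand$total_count,
      mature_length = nchar(cand$mature_seq),
      duplex_passes = isTRUE(ev$duplex_passes),
      n_libraries_pass = if (is.null(filt)) 0L else filt$n_libraries_pass,
      accepted = ok, reason = ev$reason %||% "",
      stringsAsFactors = FALSE)
    if (ok) {
      loc <- ev$locus; loc$name <- nm
      accepted[[nm]] <- loc
    }
  }
  list(accepted = accepted,
       summary = if (length(summ)) do.call(rbind, c(summ,
                   list(make.row.names = FALSE))) else NULL,
       reports = if (length(reports)) do.call(rbind, c(reports,
                   list(make.row.names = FALSE))) else NULL,
       candidates = cands)
}

## Fold one candidate's precursor window, derive the star of its most
## abundant read, apply the duplex criteria, and collect per-library
## precision reports.
evaluate_candidate <- function(cand, genome, libraries, alignments,
                               pad = 10L, max_hairpin = 200L) {
  chrom_seq <- genome[[cand$chrom]]
  ws <- max(1L, cand$start - pad)
  we <- min(nchar(chrom_seq), cand$end + pad)
  if (we - ws + 1L > max_hairpin) {
    mid <- (cand$mature_start + cand$mature_end) %/% 2L
    ws <- max(ws, mid - max_hairpin %/% 2L)
    we <- min(we, ws + max_hairpin - 1L)
  }
  win <- substr(chrom_seq, ws, we)
  hairpin <- if (cand$strand == "+") win else revcomp(win)
  n <- nchar(hairpin)
  # candidate mature in hairpin-local coordinates
  if (cand$strand == "+") {
    m1 <- cand$mature_start - ws + 1L
    m2 <- cand$mature_end - ws + 1L
  } else {
    m1 <- we - cand$mature_end + 1L
    m2 <- we - cand$mature_start + 1L
  }
  if (m1 < 1 || m2 > n)
    return(list(duplex_passes = FALSE, reason = "mature outside window"))
  fold <- fold_hairpin(hairpin)
  star <- tryCatch(derive_star(hairpin, fold, m1, m2),
                   error = function(e) e)
  if (inherits(star, "error"))
    return(list(duplex_passes = FALSE,
                reason = paste("star:", conditionMessage(star))))
  duplex <- tryCatch(check_duplex(hairpin, fold, c(m1, m2),
                                  c(star$start, star$end)),
                     error = function(e) e)
  if (inherits(duplex, "error"))
    return(list(duplex_passes = FALSE,
                reason = paste("duplex:", conditionMessage(duplex))))
  # arm genomic coordinates for read classification
  loc2gen <- function(l1, l2) {
    if (cand$strand == "+") c(ws + l1 - 1L, ws + l2 - 1L)
    else c(we - l2 + 1L, we - l1 + 1L)
  }
  gm <- loc2gen(m1, m2)
  gs <- loc2gen(star$start, star$end)
  mature_length <- m2 - m1 + 1L
  reports <- lapply(seq_along(libraries), function(k) {
    a <- alignments[[k]]
    a <- a[a$chrom == cand$chrom & a$strand == cand$strand &
             a$start <= we & a$end >= ws, , drop = FALSE]
    precision_ratio(gm, gs, a, mature_length = mature_length,
                    library_id = libraries[[k]]$library_id)
  })
  reports <- do.call(rbind, reports)
  arm5 <- if (m1 < star$start) list(seq = substr(hairpin, m1, m2),
                                    start = m1, end = m2)
          else list(seq = star$seq, start = star$start, end = star$end)
  arm3 <- if (m1 < star$start) list(seq = star$seq, start = star$start,
                                    end = star$end)
          else list(seq = substr(hairpin, m1, m2), start = m1, end = m2)
  locus <- mirna_locus(name = "candidate", chrom = cand$chrom,
                       start = ws, end = we, strand = cand$strand,
                       hairpin = hairpin, structure = fold,
                       mature_5p = arm5, mature_3p = arm3,
                       mature_arm = if (m1 < star$start) "5p" else "3p")
  list(duplex_passes = duplex$passes, duplex = duplex,
       reports = reports, locus = locus, reason = NULL)
}
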