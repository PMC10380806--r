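## Read mapping (ungapped, <= 1 mismatch), cluster calling (gap-merge
## stand-in for an external cluster finder), and known-locus
## subtraction.

#' Map a library's unique reads to a genome
#'
#' Ungapped mapping allowing at most `max_mismatch` (0 or 1)
#' mismatches. For each read, all loci achieving its best mismatch
#' count are reported (exact hits suppress 1-mismatch hits). Both
#' strands are searched; minus-strand hits are recorded against the
#' forward coordinates of their span.
#'
#' The default `method = "index"` hashes genome substrings of the read
#' lengths present and looks up each read and its single-mismatch
#' variants; `method = "scan"` slides every read along every
#' chromosome. Both give identical results; scan is only for small
#' genomes and cross-checks.
#'
#' @param genome a `Genome`.
#' @param library a `ReadLibrary` (or data.frame with `seq`, `count`).
#' @param max_mismatch 0 or 1.
#' @param min_len,max_len read-length window admitted to mapping.
#' @param method `"index"` or `"scan"`.
#' @param index prebuilt [genome_index()] (index method only); built
#'   on the fly when `NULL`. Reuse one index when mapping many
#'   libraries to the same genome.
#' @return data.frame of alignments: `seq`, `count`, `chrom`, `start`,
#'   `end` (1-based inclusive), `strand`, `n_mismatches`.
#' @export
map_reads <- function(genome, library, max_mismatch = 1L,
                      min_len = 18L, max_len = 30L,
                      method = c("index", "scan"), index = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(genome, "Genome"), max_mismatch %in% c(0L, 1L))
  if (!length(genome) || all(nchar(unclass(genome)) == 0))
    stop("empty genome")
  reads <- if (inherits(library, "ReadLibrary")) library$unique_reads
           else library
  stopifnot(all(c("seq", "count") %in% names(reads)))
  L <- nchar(reads$seq)
  reads <- reads[L >= min_len & L <= max_len, , drop = FALSE]
  if (!nrow(reads)) return(empty_alignments())
  hits <- if (method == "index")
            map_reads_index(genome, reads, max_mismatch, index)
          else map_reads_scan(genome, reads, max_mismatch)
  if (!nrow(hits)) return(empty_alignments())
  # best mismatch count per read
  hits <- hits[order(hits$seq, hits$n_mismatches, hits$chrom, hits$start,
                     hits$strand), , drop = FALSE]
  best <- tapply(hits$n_mismatches, hits$seq, min)
  hits <- hits[hits$n_mismatches == best[hits$seq], , drop = FALSE]
  hits$count <- reads$count[match(hits$seq, reads$seq)]
  rownames(hits) <- NULL
  hits[, c("seq", "count", "chrom", "start", "end", "strand",
           "n_mismatches")]
}

empty_alignments <- function()
  data.frame(seq = character(0), count = integer(0), chrom = character(0),
              start = integer(0), end = integer(0), strand = character(0),
              n_mismatches = integer(0), stringsAsFactors = FALSE)

#' Build a substring index of a genome for read mapping
#'
#' One keyed table of genome substrings per read length; passed to
#' [map_reads()] to avoid rebuilding when mapping many libraries.
#'
#' @param genome a `Genome`.
#' @param lengths integer vector of read lengths to index.
#' @return named list (by length) of keyed data.tables.
#' @export
genome_index <- function(genome, lengths) {
  lengths <- sort(unique(as.integer(lengths)))
  idx <- lapply(lengths, function(L) {
    tab <- data.table::rbindlist(lapply(names(genome), function(chr) {
      gseq <- genome[[chr]]
      n <- nchar(gseq) - L + 1L
      if (n < 1) return(NULL)
      starts <- seq_len(n)
      data.table::data.table(key_seq = substring(gseq, starts,
                                                 starts + L - 1L),
                             chrom = chr, start = starts)
    }))
    if (nrow(tab)) data.table::setkey(tab, key_seq)
    tab
  })
  names(idx) <- as.character(lengths)
  idx
}

## hash-index route: exact lookups of each read / its 1-mm variants in
## tables of genome substrings, one table per read length
map_reads_index <- function(genome, reads, max_mismatch, index = NULL) {
  lens <- sort(unique(nchar(reads$seq)))
  out <- vector("list", length(lens))
  for (li in seq_along(lens)) {
    L <- lens[li]
    idx <- if (!is.null(index) && as.character(L) %in% names(index))
      index[[as.character(L)]]
    else genome_index(genome, L)[[1]]
    if (!nrow(idx)) next
    rd <- reads$seq[nchar(reads$seq) == L]
    qry <- build_query_table(rd, max_mismatch)
    m <- idx[qry, on = "key_seq", nomatch = NULL, allow.cartesian = TRUE]
    if (!nrow(m)) next
    out[[li]] <- data.frame(seq = m$read, chrom = m$chrom,
                            start = m$start, end = m$start + L - 1L,
                            strand = m$strand,
                            n_mismatches = m$n_mm,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(empty_alignments())
  # the same location can be reached as both an exact hit and (never)
  # a variant; dedupe defensively on all columns
  unique(res)
}

## query table: for each read, both orientations, exact plus (if
## allowed) every single-substitution variant
build_query_table <- function(rd, max_mismatch) {
  qs <- list()
  for (strand in c("+", "-")) {
    oriented <- if (strand == "+") rd else revcomp(rd)
    qs[[length(qs) + 1L]] <-
      data.table::data.table(key_seq = oriented, read = rd,
                             strand = strand, n_mm = 0L)
    if (max_mismatch >= 1L) {
      L <- nchar(oriented[1])
      for (pos in seq_len(L)) {
        orig <- substr(oriented, pos, pos)
        for (b in DNA_BASES) {
          keep <- orig != b
          if (!any(keep)) next
          var <- oriented[keep]
          substr(var, pos, pos) <- b
          qs[[length(qs) + 1L]] <-
            data.table::data.table(key_seq = var, read = rd[keep],
                                   strand = strand, n_mm = 1L)
        }
      }
    }
  }
  data.table::rbindlist(qs)
}

## sliding-window route (small genomes / verification)
map_reads_scan <- function(genome, reads, max_mismatch) {
  out <- list()
  for (chr in names(genome)) {
    gseq <- genome[[chr]]
    for (k in seq_len(nrow(reads))) {
      rs <- reads$seq[k]
      L <- nchar(rs)
      for (strand in c("+", "-")) {
        q <- if (strand == "+") rs else revcomp(rs)
        mm <- .window_mismatches(q, gseq)
        hit <- which(mm <= max_mismatch)
        if (length(hit))
          out[[length(out) + 1L]] <-
            data.frame(seq = rs, chrom = chr, start = hit,
                       end = hit + L - 1L, strand = strand,
                       n_mismatches = mm[hit], stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty_alignments() else res
}

#' Call candidate MIRNA loci from alignments by gap merging
#'
#' Same-strand alignments separated by at most `max_gap` bp merge into
#' one locus; loci whose total read count is below `min_reads` are
#' dropped. The candidate mature is the most abundant distinct read in
#' the locus (ties broken by the lexicographically smaller sequence).
#' This deterministic merge stands in for an external cluster caller;
#' loci from any caller can equally be supplied as GFF3.
#'
#' @param alignments data.frame from [map_reads()] (multiple libraries
#'   may be concatenated; counts for identical `(seq, position)` rows
#'   are summed).
#' @param min_reads minimum total read count per locus.
#' @param max_gap maximum merge gap in bp.
#' @return list of `CandidateLocus` objects: `chrom`, `start`, `end`,
#'   `strand`, `total_count`, `mature_seq`, `mature_start`,
#'   `mature_end`, `alignments`.
#' @export
call_clusters <- function(alignments, min_reads = 10L, max_gap = 75L) {
  if (!nrow(alignments)) return(list())
  dt <- data.table::as.data.table(alignments)
  dt <- dt[, list(count = sum(count)),
           by = c("seq", "chrom", "start", "end", "strand",
                  "n_mismatches")]
  gr <- GenomicRanges::GRanges(dt$chrom,
                               IRanges::IRanges(dt$start, dt$end),
                               strand = dt$strand)
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L)
  ov <- GenomicRanges::findOverlaps(gr, red)
  out <- list()
  for (ci in seq_along(red)) {
    rows <- dt[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == ci], ]
    total <- sum(rows$count)
    if (total < min_reads) next
    agg <- rows[, list(count = sum(count)), by = "seq"]
    agg <- agg[order(-agg$count, agg$seq), ]
    mature <- agg$seq[1]
    mrow <- rows[rows$seq == mature, ][1, ]
    out[[length(out) + 1L]] <- structure(
      list(chrom = as.character(GenomicRanges::seqnames(red))[ci],
           start = GenomicRanges::start(red)[ci],
           end = GenomicRanges::end(red)[ci],
           strand = as.character(GenomicRanges::strand(red))[ci],
           total_count = total,
           mature_seq = mature,
           mature_start = mrow$start,
           mature_end = mrow$end,
           alignments = as.data.frame(rows)),
      class = "CandidateLocus")
  }
  out
}

#' @export
print.CandidateLocus <- function(x, ...) {
  cat(sprintf("CandidateLocus %s:%d-%d(%s) total=%d mature=%s\n",
              x$chrom, x$start, x$end, x$strand, x$total_count,
              x$mature_seq))
  invisible(x)
}

#' Partition candidate loci by overlap with known MIRNA annotations
#'
#' A candidate overlapping any known locus by at least 1 bp is
#' "known-overlapping"; the rest are novel. By default overlap on
#' either strand counts (MIRNA loci on the opposite strand of known
#' ones exist, so novelty is judged conservatively); `stranded = TRUE`
#' restricts overlap to the same strand.
#'
#' @param candidates list of `CandidateLocus`.
#' @param known data.frame with `chrom`, `start`, `end`, `strand`
#'   (e.g. from [read_loci_gff3()]); may be empty.
#' @param stranded require same-strand overlap.
#' @return list with elements `known_overlapping` and `novel`.
#' @export
intersect_known <- function(candidates, known, stranded = FALSE) {
  if (!length(candidates))
    return(list(known_overlapping = list(), novel = list()))
  if (is.null(known) || !nrow(known))
    return(list(known_overlapping = list(), novel = candidates))
  cand_chrom <- vapply(candidates, `[[`, character(1), "chrom")
  missing <- setdiff(unique(cand_chrom), unique(known$chrom))
  if (length(missing))
    warning("candidate chromosome(s) absent from known annotation: ",
            paste(missing, collapse = ", "),
            "; treated as non-overlapping")
  cgr <- GenomicRanges::GRanges(
    cand_chrom,
    IRanges::IRanges(vapply(candidates, `[[`, numeric(1), "start"),
                     vapply(candidates, `[[`, numeric(1), "end")),
    strand = vapply(candidates, `[[`, character(1), "strand"))
  kgr <- GenomicRanges::GRanges(known$chrom,
                                IRanges::IRanges(known$start, known$end),
                                strand = known$strand)
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(cgr, kgr, minoverlap = 1L,
                                ignore.strand = !stranded))
  hit <- unique(S4Vectors::queryHits(ov))
  list(known_overlapping = candidates[sort(hit)],
       novel = candidates[setdiff(seq_along(candidates), hit)])
}
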