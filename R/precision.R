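## Processing-precision ratio per locus per library, and the
## read-support / length-class / multi-library acceptance rules that
## separate MIRNA loci from siRNA-like clusters.

#' Precision-ratio thresholds by mature length class
#'
#' Mature miRNAs of 20-22 nt require a processing-precision ratio of
#' at least 0.75; 23-24 nt matures require at least 0.90 (higher
#' stringency is recommended for those lengths). Lengths outside
#' 20-24 nt have no defined threshold and the candidate is rejected.
#'
#' @param mature_length integer length in nt.
#' @return numeric threshold, or `NA` outside 20-24 nt.
#' @export
precision_threshold <- function(mature_length) {
  ifelse(mature_length >= 20 & mature_length <= 22, 0.75,
         ifelse(mature_length >= 23 & mature_length <= 24, 0.90,
                NA_real_))
}

#' Processing-precision ratio of a locus in one library
#'
#' Classifies every read overlapping the hairpin on the locus strand:
#' exact mature or star (both ends match the arm exactly), 1-nt
#' positional variant (each end independently within 1 nt of either
#' arm's corresponding end), or other. The ratio is
#' `(mature + star + variant) / total`, weighted by read multiplicity.
#' The per-library pass requires at least 10 exact mature reads AND
#' the ratio at or above the mature length-class threshold.
#'
#' @param mature,star two-element vectors `c(start, end)` of the arm
#'   genomic coordinates (1-based inclusive, on `strand`).
#' @param alignments data.frame of alignments restricted to reads
#'   overlapping the hairpin interval on the locus strand (columns
#'   `start`, `end`, `count`).
#' @param mature_length mature length in nt; defaults to the mature
#'   interval width.
#' @param locus_name,library_id labels carried into the report.
#' @return one-row data.frame of class `PrecisionReport`:
#'   `locus`, `library_id`, `mature_reads`, `star_reads`,
#'   `variant_reads`, `other_reads`, `total_reads`, `ratio`,
#'   `mature_length`, `threshold`, `passes`.
#' @export
precision_ratio <- function(mature, star, alignments,
                            mature_length = NULL,
                            locus_name = NA_character_,
                            library_id = NA_character_) {
  stopifnot(length(mature) == 2, length(star) == 2)
  mature_length <- mature_length %||% (mature[2] - mature[1] + 1L)
  thr <- precision_threshold(mature_length)
  if (is.null(alignments) || !nrow(alignments)) {
    return(precision_report(locus_name, library_id, 0L, 0L, 0L, 0L,
                            NA_real_, mature_length, thr, FALSE))
  }
  s <- alignments$start; e <- alignments$end; cnt <- alignments$count
  exact_m <- s == mature[1] & e == mature[2]
  exact_s <- s == star[1] & e == star[2]
  var_m <- abs(s - mature[1]) <= 1 & abs(e - mature[2]) <= 1
  var_s <- abs(s - star[1]) <= 1 & abs(e - star[2]) <= 1
  variant <- (var_m | var_s) & !exact_m & !exact_s
  other <- !(exact_m | exact_s | variant)
  m <- sum(cnt[exact_m]); st <- sum(cnt[exact_s])
  v <- sum(cnt[variant]); o <- sum(cnt[other])
  total <- m + st + v + o
  ratio <- if (total == 0) NA_real_ else (m + st + v) / total
  passes <- !is.na(ratio) && !is.na(thr) && m >= 10 && ratio >= thr
  precision_report(locus_name, library_id, m, st, v, o, ratio,
                   mature_length, thr, passes)
}

precision_report <- function(locus, library_id, m, s, v, o, ratio,
                             mature_length, thr, passes) {
  out <- data.frame(locus = locus, library_id = library_id,
                    mature_reads = m, star_reads = s, variant_reads = v,
                    other_reads = o, total_reads = m + s + v + o,
                    ratio = ratio, mature_length = mature_length,
                    threshold = thr, passes = passes,
                    stringsAsFactors = FALSE)
  class(out) <- c("PrecisionReport", class(out))
  out
}

#' Apply the novel-MIRNA acceptance rules
#'
#' A candidate is accepted when (i) its hairpin duplex passes
#' [check_duplex()], (ii) its mature length is within 20-24 nt, and
#' (iii) the per-library pass (>= 10 exact mature reads AND
#' precision ratio at or above the length-class threshold, a
#' per-library conjunction) holds in at least `min_libraries`
#' libraries. With `pooled_support = TRUE` the 10-read support is
#' instead assessed on mature reads pooled across libraries while the
#' ratio threshold stays per-library.
#'
#' @param reports data.frame of per-locus-per-library rows (rbind of
#'   [precision_ratio()] outputs).
#' @param duplex_pass named logical vector: locus to duplex verdict.
#' @param min_libraries minimum number of passing libraries.
#' @param pooled_support assess the 10-read support on pooled counts.
#' @return data.frame with one row per locus: `locus`,
#'   `duplex_passes`, `mature_length`, `n_libraries_pass`, `accepted`.
#' @export
apply_mirna_filters <- function(reports, duplex_pass,
                                min_libraries = 4L,
                                pooled_support = FALSE) {
  stopifnot(is.data.frame(reports))
  loci <- unique(reports$locus)
  rows <- lapply(loci, function(lc) {
    r <- reports[reports$locus == lc, , drop = FALSE]
    ml <- r$mature_length[1]
    if (pooled_support) {
      pooled_ok <- sum(r$mature_reads) >= 10
      libpass <- pooled_ok & !is.na(r$ratio) & !is.na(r$threshold) &
        r$ratio >= r$threshold
    } else {
      libpass <- r$passes
    }
    dp <- isTRUE(unname(duplex_pass[lc]))
    npass <- sum(libpass, na.rm = TRUE)
    data.frame(locus = lc, duplex_passes = dp, mature_length = ml,
               n_libraries_pass = npass,
               accepted = dp && ml >= 20 && ml <= 24 &&
                 npass >= min_libraries,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
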