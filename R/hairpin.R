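## Hairpin folding, miRNA-star derivation with 2-nt 3' overhangs, and
## evaluation of the mature/star duplex against annotation criteria.

#' Fold a sequence into a nested secondary structure
#'
#' Base-pair-maximizing (Nussinov-style) folding: Watson-Crick plus G:U
#' pairs, minimum hairpin loop of 3 nt, pseudoknot-free. The traceback
#' is deterministic and prefers pairings closer to the outer ends. This
#' is a stand-in for a thermodynamic folder; precomputed structures can
#' be supplied instead via [read_dbn()] wherever a structure is
#' accepted.
#'
#' @param sequence DNA or RNA string (ACGTU, case-insensitive).
#' @return dot-bracket string the same length as `sequence`.
#' @export
fold_hairpin <- function(sequence) {
  seq <- normalize_dna(sequence, allow_n = FALSE)
  .nussinov_fold(seq)$structure
}

#' Maximum base-pair count of the built-in folder
#' @param sequence DNA or RNA string.
#' @return integer pair count.
#' @export
max_pairs <- function(sequence) {
  seq <- normalize_dna(sequence, allow_n = FALSE)
  .nussinov_fold(seq)$n_pairs
}

#' Pairing partner table of a dot-bracket structure
#'
#' @param structure dot-bracket string.
#' @return integer vector; `pt[i]` is the partner of position `i`
#'   (1-based) or `NA` if unpaired.
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  pt <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced brackets in structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced brackets in structure")
  pt
}

#' Derive the miRNA* of a mature miRNA from the hairpin structure
#'
#' The star spans the positions pairing with the mature, shifted so
#' that both duplex strands carry 2-nt 3' overhangs: on a perfect stem
#' the star is the reverse complement of the mature displaced by 2 nt.
#' Applying the derivation twice on a perfect stem returns the original
#' mature.
#'
#' @param hairpin precursor sequence (5' to 3').
#' @param structure dot-bracket structure of `hairpin`; folded with
#'   [fold_hairpin()] when `NULL`.
#' @param mature_start,mature_end 1-based mature position in the
#'   hairpin; alternatively give `mature_seq` to locate it.
#' @param mature_seq mature sequence, used to locate the mature when
#'   positions are not given (must occur exactly once).
#' @return list with `seq`, `start`, `end` (hairpin-local, 1-based).
#' @export
derive_star <- function(hairpin, structure = NULL, mature_start = NULL,
                        mature_end = NULL, mature_seq = NULL) {
  hairpin <- normalize_dna(hairpin)
  n <- nchar(hairpin)
  if (is.null(structure)) structure <- fold_hairpin(hairpin)
  validate_structure(hairpin, structure)
  if (is.null(mature_start)) {
    if (is.null(mature_seq)) stop("give mature positions or mature_seq")
    mature_seq <- normalize_dna(mature_seq)
    hit <- gregexpr(mature_seq, hairpin, fixed = TRUE)[[1]]
    if (hit[1] == -1) stop("mature sequence not found in hairpin")
    mature_start <- hit[1]
    mature_end <- mature_start + nchar(mature_seq) - 1L
  }
  if (mature_start < 1 || mature_end > n || mature_start >= mature_end)
    stop("mature positions outside hairpin")
  pt <- pair_table(structure)
  # anchor near the mature 3' end minus the 2-nt overhang
  i2 <- mature_end - 2L
  while (i2 >= mature_start && is.na(pt[i2])) i2 <- i2 - 1L
  # anchor at the mature 5' end
  i1 <- mature_start
  while (i1 <= mature_end && is.na(pt[i1])) i1 <- i1 + 1L
  if (i2 < mature_start || i1 > mature_end || i1 > i2)
    stop("mature arm is unpaired; cannot derive star")
  star_start <- pt[i2] - ((mature_end - 2L) - i2)
  star_end <- pt[i1] + 2L + (i1 - mature_start)
  if (star_start < 1 || star_end > n)
    stop("star would extend past hairpin end (positions ", star_start,
         "..", star_end, " of ", n, ")")
  if (star_end <= star_start)
    stop("degenerate star span (positions ", star_start, "..",
         star_end, ")")
  if (star_start <= mature_end && star_end >= mature_start)
    stop("derived star overlaps the mature arm")
  list(seq = substr(hairpin, star_start, star_end),
       start = star_start, end = star_end)
}

#' Evaluate a mature/miRNA* duplex against annotation criteria
#'
#' Counts mismatched positions within the duplex region (mature plus
#' star, excluding the terminal 2-nt 3' overhang of each strand) and
#' the subset of them lying in asymmetric bulges. An interior loop
#' with `gA` unpaired nucleotides on one strand and `gB` on the other
#' contributes `max(gA, gB)` mismatched positions, `|gA - gB|` of them
#' asymmetric-bulge nucleotides (unpaired nucleotides with no
#' counterpart on the opposite strand); dangling core ends count the
#' same way. G:U counts as paired. This column-wise counting is
#' symmetric in (mature, star) and guarantees
#' `n_asym_bulge_nt <= n_unpaired`. By default the duplex passes when
#' the mismatch count is at most 5 AND the asymmetric-bulge count is
#' at most 3, the joint-cap reading of community annotation criteria
#' (the literal disjunction would pass a 10-mismatch duplex with 3
#' bulges); `literal_or = TRUE` restores the disjunctive reading.
#'
#' @param hairpin precursor sequence.
#' @param structure dot-bracket structure of `hairpin`.
#' @param mature,star two-element integer vectors `c(start, end)`
#'   (hairpin-local, 1-based) of the two duplex arms.
#' @param literal_or use the disjunctive reading of the caps.
#' @return object of class `DuplexReport`: list with `n_unpaired`,
#'   `n_asym_bulge_nt`, `passes`.
#' @export
check_duplex <- function(hairpin, structure, mature, star,
                         literal_or = FALSE) {
  hairpin <- normalize_dna(hairpin)
  validate_structure(hairpin, structure)
  stopifnot(length(mature) == 2, length(star) == 2)
  pt <- pair_table(structure)
  # orient: strand A = the arm with smaller coordinates
  a <- sort(as.integer(mature)); b <- sort(as.integer(star))
  if (a[1] > b[1]) { tmp <- a; a <- b; b <- tmp }
  if (a[2] >= b[1]) stop("mature and star overlap")
  # cores exclude each strand's 2-nt 3' overhang (the 3' end of each
  # arm is its higher-index end along the 5'->3' precursor)
  a_core <- seq.int(a[1], max(a[1], a[2] - 2L))
  b_core <- seq.int(b[1], max(b[1], b[2] - 2L))
  in_b <- function(p) !is.na(p) & p >= b[1] & p <= b[2]
  paired_a <- a_core[in_b(pt[a_core])]
  # walk consecutive duplex pairs: an interior loop with gA and gB
  # unpaired nt contributes max(gA, gB) mismatched positions and
  # |gA - gB| asymmetric-bulge nucleotides; dangling core ends count
  # the same way (gaps clamp at 0 when a partner sits in the excluded
  # overhang)
  n_unpaired <- 0L
  asym <- 0L
  if (length(paired_a)) {
    pa <- paired_a                      # ascending on strand A
    qa <- pt[pa]                        # descending on strand B
    # leading gap: A 5' side aligns with B 3' side (core end)
    g1 <- max(0L, pa[1] - a_core[1])
    g2 <- max(0L, b_core[length(b_core)] - qa[1])
    n_unpaired <- n_unpaired + max(g1, g2)
    asym <- asym + abs(g1 - g2)
    if (length(pa) > 1) {
      g1 <- diff(pa) - 1L
      g2 <- -diff(qa) - 1L
      n_unpaired <- n_unpaired + sum(pmax(g1, g2))
      asym <- asym + sum(abs(g1 - g2))
    }
    k <- length(pa)
    g1 <- max(0L, a_core[length(a_core)] - pa[k])
    g2 <- max(0L, qa[k] - b_core[1])
    n_unpaired <- n_unpaired + max(g1, g2)
    asym <- asym + abs(g1 - g2)
  } else {
    n_unpaired <- max(length(a_core), length(b_core))
    asym <- abs(length(a_core) - length(b_core))
  }
  passes <- if (literal_or) (n_unpaired <= 5L || asym <= 3L)
            else (n_unpaired <= 5L && asym <= 3L)
  structure(list(n_unpaired = as.integer(n_unpaired),
                 n_asym_bulge_nt = as.integer(asym),
                 passes = passes),
            class = "DuplexReport")
}

#' @export
print.DuplexReport <- function(x, ...) {
  cat("DuplexReport:", x$n_unpaired, "unpaired nt,", x$n_asym_bulge_nt,
      "asymmetric-bulge nt ->", if (x$passes) "PASS" else "FAIL", "\n")
  invisible(x)
}
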