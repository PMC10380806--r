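## Independent oracles used by the test suite. These deliberately take
## different computational routes from the package implementation.

## --- folding oracle: exhaustive enumeration of nested structures ----

oracle_can_pair <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

## maximum pair count over all pseudoknot-free structures with a
## minimum hairpin loop of 3 nt, by explicit recursion over "position
## i unpaired, or i paired with some k" (exponential; n <= 18 only)
oracle_max_pairs <- function(seq) {
  ch <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    if (j - i < 4) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i + 1L, j)
    for (k in (i + 4L):j) {
      if (oracle_can_pair(ch[i], ch[k]))
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    memo[[key]] <- best
    best
  }
  if (length(ch) < 5) 0L else rec(1L, length(ch))
}

## --- mapping oracle: Biostrings pattern matching ---------------------

oracle_map_reads <- function(genome, reads, max_mismatch = 1L) {
  out <- list()
  for (chr in names(genome)) {
    subj <- Biostrings::DNAString(genome[[chr]])
    for (rs in reads) {
      for (strand in c("+", "-")) {
        q <- if (strand == "+") rs else as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(rs)))
        m <- Biostrings::matchPattern(q, subj,
                                      max.mismatch = max_mismatch,
                                      with.indels = FALSE)
        if (length(m)) {
          mm <- vapply(seq_along(m), function(i)
            sum(strsplit(as.character(m[[i]]), "")[[1]] !=
                  strsplit(q, "")[[1]]), integer(1))
          out[[length(out) + 1L]] <-
            data.frame(seq = rs, chrom = chr,
                       start = Biostrings::start(m),
                       end = Biostrings::end(m), strand = strand,
                       n_mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(res)
  # keep best-mismatch hits per read
  best <- tapply(res$n_mismatches, res$seq, min)
  res <- res[res$n_mismatches == best[res$seq], , drop = FALSE]
  res[order(res$seq, res$chrom, res$start, res$strand), , drop = FALSE]
}

## --- exact-test oracle: dnbinom-product enumeration ------------------

oracle_exact_pvalue <- function(kA, kB, nA, nB, phi, mu = 7.3) {
  t <- kA + kB
  if (t == 0) return(1)
  k <- 0:t
  pr <- if (phi <= 0) {
    stats::dbinom(k, t, nA / (nA + nB))
  } else {
    # joint NB probabilities at an arbitrary mean; conditioning on the
    # total cancels mu
    w <- stats::dnbinom(k, size = nA / phi, mu = nA * mu) *
      stats::dnbinom(t - k, size = nB / phi, mu = nB * mu)
    w / sum(w)
  }
  sum(pr[pr <= pr[kA + 1] * (1 + 1e-10)])
}

## --- precision-ratio oracle: explicit per-read classification --------

oracle_precision_counts <- function(mature, star, aln) {
  cls <- character(nrow(aln))
  for (i in seq_len(nrow(aln))) {
    s <- aln$start[i]; e <- aln$end[i]
    if (s == mature[1] && e == mature[2]) cls[i] <- "mature"
    else if (s == star[1] && e == star[2]) cls[i] <- "star"
    else if ((abs(s - mature[1]) <= 1 && abs(e - mature[2]) <= 1) ||
             (abs(s - star[1]) <= 1 && abs(e - star[2]) <= 1))
      cls[i] <- "variant"
    else cls[i] <- "other"
  }
  c(mature = sum(aln$count[cls == "mature"]),
    star = sum(aln$count[cls == "star"]),
    variant = sum(aln$count[cls == "variant"]),
    other = sum(aln$count[cls == "other"]))
}

## --- attribution oracle: exhaustive scoring of all placements --------

oracle_attribute <- function(read, catalog_names, catalog_seqs) {
  best <- NULL; best_name <- NULL
  ord <- order(catalog_names)
  for (j in ord) {
    entry <- catalog_seqs[j]
    lr <- nchar(read); le <- nchar(entry)
    for (d in -1:1) {
      e <- (d + lr) - le
      if (abs(e) > 1) next
      os <- max(1L, 1L + d); oe <- min(le, le + e)
      if (oe < os) next
      mm <- sum(strsplit(substr(entry, os, oe), "")[[1]] !=
                  strsplit(substr(read, os - d, oe - d), "")[[1]])
      if (mm > 1) next
      sc <- c(mm, abs(d) + abs(e))
      if (is.null(best) || sc[1] < best[1] ||
          (sc[1] == best[1] && sc[2] < best[2])) {
        best <- sc; best_name <- catalog_names[j]
      }
    }
  }
  best_name
}

## --- interval-overlap oracle -----------------------------------------

oracle_overlaps <- function(cand, known, stranded = FALSE) {
  hit <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    for (j in seq_len(nrow(known))) {
      if (cand$chrom[i] != known$chrom[j]) next
      if (stranded && cand$strand[i] != known$strand[j]) next
      if (cand$start[i] <= known$end[j] && cand$end[i] >= known$start[j]) {
        hit[i] <- TRUE; break
      }
    }
  }
  hit
}

## --- set-comparison oracle: brute force over the membership matrix ---

oracle_set_counts <- function(up) {
  n <- ncol(up)
  list(shared = sum(rowSums(up) == n),
       specific = vapply(seq_len(n), function(g)
         sum(up[, g] & rowSums(up) == 1), numeric(1)))
}
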