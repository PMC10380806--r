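## Mature+star catalog construction, best-hit read attribution, and
## raw-count / CPM matrices.

#' Build a mature/star catalog
#'
#' Combines known mature/star sequences with the 5p/3p arms of
#' accepted novel loci. Entries sharing an identical sequence are
#' merged under a combined name (names joined with `/`). Known matures
#' lacking a star are completed from their hairpin via [derive_star()]
#' when a hairpin is supplied; otherwise they are kept mature-only
#' with a warning.
#'
#' @param known named character vector of known mature (and star)
#'   sequences; DNA or RNA.
#' @param novel_loci list of `MirnaLocus`; contributes `<name>-5p` and
#'   `<name>-3p` entries.
#' @param hairpins optional named character vector of hairpin
#'   sequences for known matures lacking a star (names matching
#'   `known` names).
#' @param derive_missing_star derive stars for known entries from
#'   `hairpins`.
#' @return object of class `Catalog`: data.frame with `name`, `seq`
#'   (DNA internally), 18-26 nt entries.
#' @export
build_catalog <- function(known = character(0), novel_loci = list(),
                          hairpins = NULL, derive_missing_star = TRUE) {
  entries <- list()
  if (length(known)) {
    if (is.null(names(known)) || any(!nzchar(names(known))))
      stop("known sequences must be named")
    for (nm in names(known))
      entries[[length(entries) + 1L]] <-
        data.frame(name = nm, seq = normalize_dna(known[[nm]]),
                   stringsAsFactors = FALSE)
    if (derive_missing_star && !is.null(hairpins)) {
      # a star entry is assumed present when a '*' / -star sibling or
      # the opposite -5p/-3p arm exists; otherwise derive it
      base <- sub("-(5p|3p)$|\\*$", "", names(known))
      for (nm in names(known)) {
        b <- sub("-(5p|3p)$|\\*$", "", nm)
        if (sum(base == b) > 1) next
        if (!b %in% names(hairpins) && !nm %in% names(hairpins)) {
          warning("no hairpin for ", nm, "; kept mature-only")
          next
        }
        hp <- normalize_dna(hairpins[[if (b %in% names(hairpins)) b else nm]])
        st <- tryCatch(derive_star(hp, mature_seq = known[[nm]]),
                       error = function(e) {
                         warning("could not derive star for ", nm, ": ",
                                 conditionMessage(e)); NULL
                       })
        if (!is.null(st))
          entries[[length(entries) + 1L]] <-
            data.frame(name = paste0(nm, "*"), seq = st$seq,
                       stringsAsFactors = FALSE)
      }
    }
  }
  for (l in novel_loci) {
    stopifnot(inherits(l, "MirnaLocus"))
    entries[[length(entries) + 1L]] <-
      data.frame(name = paste0(l$name, "-5p"), seq = l$mature_5p$seq,
                 stringsAsFactors = FALSE)
    entries[[length(entries) + 1L]] <-
      data.frame(name = paste0(l$name, "-3p"), seq = l$mature_3p$seq,
                 stringsAsFactors = FALSE)
  }
  cat_df <- do.call(rbind, entries)
  if (is.null(cat_df))
    cat_df <- data.frame(name = character(0), seq = character(0),
                         stringsAsFactors = FALSE)
  if (nrow(cat_df)) {
    bad <- nchar(cat_df$seq) < 18 | nchar(cat_df$seq) > 26
    if (any(bad)) {
      warning("dropping ", sum(bad), " entries outside 18-26 nt")
      cat_df <- cat_df[!bad, , drop = FALSE]
    }
    # merge redundant sequences under a combined name
    merged <- lapply(split(cat_df$name, cat_df$seq), function(nms)
      paste(sort(unique(nms)), collapse = "/"))
    cat_df <- data.frame(name = unlist(merged), seq = names(merged),
                         stringsAsFactors = FALSE)
    cat_df <- cat_df[order(cat_df$name), , drop = FALSE]
    rownames(cat_df) <- NULL
  }
  structure(cat_df, class = c("Catalog", "data.frame"))
}

## Best ungapped alignment of one read against one entry under the
## attribution rules: no gaps, <= 1 mismatch, <= 1 nt
## extension/truncation at each end. Returns c(mismatches, end_offset)
## or NULL when no admissible alignment exists.
score_read_entry <- function(read, entry) {
  lr <- nchar(read); le <- nchar(entry)
  if (abs(lr - le) > 2) return(NULL)
  best <- NULL
  for (d in -1:1) {              # read start relative to entry start
    e <- (d + lr) - le           # read end relative to entry end
    if (abs(e) > 1) next
    # overlap in entry coordinates
    os <- max(1L, 1L + d); oe <- min(le, le + e)
    if (oe < os) next
    a <- substr(entry, os, oe)
    b <- substr(read, os - d, oe - d)
    mm <- hamming(a, b)
    if (mm > 1) next
    sc <- c(mm, abs(d) + abs(e))
    if (is.null(best) || sc[1] < best[1] ||
        (sc[1] == best[1] && sc[2] < best[2]))
      best <- sc
  }
  best
}

#' Attribute a library's unique reads to catalog entries
#'
#' Each unique read is assigned to at most one catalog entry by the
#' best admissible ungapped alignment: no gaps, at most 1 mismatch,
#' and at most a 1-nt extension or truncation at each end (the two
#' allowances may co-occur). The best hit minimizes
#' `(mismatches, total end offset)` lexicographically; exact score
#' ties go to the lexicographically smallest entry name. The read's
#' full multiplicity is added to the chosen entry; reads failing all
#' rules stay unassigned.
#'
#' @param library a `ReadLibrary`.
#' @param catalog a `Catalog`.
#' @return named integer vector of counts, one per catalog entry (in
#'   catalog order), with attribute `unassigned` (total unassigned
#'   read count).
#' @export
attribute_reads <- function(library, catalog) {
  stopifnot(inherits(library, "ReadLibrary"), inherits(catalog, "Catalog"))
  counts <- setNames(integer(nrow(catalog)), catalog$name)
  ur <- library$unique_reads
  unassigned <- 0L
  if (!nrow(ur) || !nrow(catalog)) {
    attr(counts, "unassigned") <- sum(ur$count)
    return(counts)
  }
  # order-independent tie-break: evaluate entries in name order
  cat_ord <- catalog[order(catalog$name), , drop = FALSE]
  exact <- match(ur$seq, cat_ord$seq)
  elen <- nchar(cat_ord$seq)
  for (k in seq_len(nrow(ur))) {
    if (!is.na(exact[k])) {      # fast path: identical sequence
      counts[cat_ord$name[exact[k]]] <-
        counts[cat_ord$name[exact[k]]] + ur$count[k]
      next
    }
    rl <- nchar(ur$seq[k])
    best <- NULL; best_name <- NULL
    for (j in which(abs(elen - rl) <= 2)) {
      sc <- score_read_entry(ur$seq[k], cat_ord$seq[j])
      if (is.null(sc)) next
      if (is.null(best) || sc[1] < best[1] ||
          (sc[1] == best[1] && sc[2] < best[2])) {
        best <- sc; best_name <- cat_ord$name[j]
      }
    }
    if (is.null(best)) unassigned <- unassigned + ur$count[k]
    else counts[best_name] <- counts[best_name] + ur$count[k]
  }
  attr(counts, "unassigned") <- unassigned
  counts
}

#' Build a raw count matrix over libraries
#'
#' @param libraries list of `ReadLibrary`.
#' @param catalog a `Catalog`.
#' @return object of class `CountMatrix`: list with `counts`
#'   (entries x libraries integer matrix), `clean_sizes` (named,
#'   per-library total clean reads) and `catalog`.
#' @export
count_matrix <- function(libraries, catalog) {
  cols <- lapply(libraries, attribute_reads, catalog = catalog)
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(libraries, `[[`, character(1), "library_id")
  structure(list(counts = m,
                 clean_sizes = setNames(
                   vapply(libraries, `[[`, integer(1), "clean_size"),
                   colnames(m)),
                 catalog = catalog),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "entries x", ncol(x$counts),
      "libraries\n")
  invisible(x)
}

#' Counts-per-million (CPM) normalization
#'
#' `CPM[i, j] = counts[i, j] * 1e6 / clean_size[j]`, using the total
#' clean reads of each library as the denominator (not the
#' miRNA-mapped totals).
#'
#' @param x a `CountMatrix`, or a plain counts matrix (then
#'   `clean_sizes` is required).
#' @param clean_sizes per-library clean read totals (> 0).
#' @return numeric matrix of CPM values.
#' @export
cpm_normalize <- function(x, clean_sizes = NULL) {
  if (inherits(x, "CountMatrix")) {
    clean_sizes <- x$clean_sizes
    x <- x$counts
  }
  stopifnot(!is.null(clean_sizes), length(clean_sizes) == ncol(x))
  if (any(clean_sizes <= 0)) stop("clean_sizes must be > 0")
  sweep(x, 2, clean_sizes, function(cnt, s) cnt * 1e6 / s)
}
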