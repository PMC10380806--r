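## Readers/writers for the standard formats the pipeline touches, plus
## read collapsing into unique-read tables.

#' Construct a ReadLibrary
#'
#' One sample's collapsed unique reads with counts and design labels.
#' `clean_size` is the total number of clean reads (sum of counts) and
#' is the denominator used for CPM normalization.
#'
#' @param library_id library identifier.
#' @param genotype,condition,replicate design labels.
#' @param unique_reads data.frame with columns `seq` (uppercase DNA,
#'   U converted to T) and `count` (>= 1).
#' @param clean_size total clean reads; defaults to `sum(count)` and
#'   must equal it.
#' @return object of class `ReadLibrary`.
#' @export
read_library <- function(library_id, genotype = NA_character_,
                         condition = NA_character_, replicate = NA_integer_,
                         unique_reads = data.frame(seq = character(0),
                                                   count = integer(0)),
                         clean_size = NULL) {
  stopifnot(is.data.frame(unique_reads),
            all(c("seq", "count") %in% names(unique_reads)))
  unique_reads$seq <- normalize_dna(unique_reads$seq)
  if (anyDuplicated(unique_reads$seq)) stop("duplicate sequences in unique_reads")
  if (any(unique_reads$count < 1)) stop("unique-read counts must be >= 1")
  total <- sum(unique_reads$count)
  clean_size <- clean_size %||% total
  if (clean_size != total)
    stop("clean_size (", clean_size, ") != sum of counts (", total, ")")
  structure(list(library_id = library_id, genotype = genotype,
                 condition = condition, replicate = as.integer(replicate),
                 unique_reads = unique_reads,
                 clean_size = as.integer(total)),
            class = "ReadLibrary")
}

#' @export
print.ReadLibrary <- function(x, ...) {
  cat("ReadLibrary", x$library_id, "-", nrow(x$unique_reads),
      "unique reads,", x$clean_size, "clean reads\n")
  invisible(x)
}

#' Collapse a FASTQ file into a ReadLibrary
#'
#' Pools identical reads into non-redundant unique reads with
#' multiplicities. U is converted to T; sequences are uppercased.
#'
#' @param fastq_path path to an adapter-trimmed FASTQ file (4-line
#'   records; gzip accepted).
#' @param ... labels passed to [read_library()] (`library_id`,
#'   `genotype`, `condition`, `replicate`).
#' @return a `ReadLibrary`; `clean_size` equals the input read count.
#' @export
collapse_reads <- function(fastq_path, ...) {
  lines <- readLines(fastq_path)
  if (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ (", fastq_path, "): ", length(lines),
         " lines is not a multiple of 4")
  n <- length(lines) %/% 4
  if (n == 0) {
    args <- list(...)
    if (is.null(args$library_id))
      args$library_id <- sub("\\.(fastq|fq)(\\.gz)?$", "",
                             basename(fastq_path))
    return(do.call(read_library, args))
  }
  hdr <- lines[seq(1, by = 4, length.out = n)]
  plus <- lines[seq(3, by = 4, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1], " in ", fastq_path)
  seqs <- normalize_dna(lines[seq(2, by = 4, length.out = n)])
  tab <- table(seqs)
  ur <- data.frame(seq = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  ur <- ur[order(ur$seq), , drop = FALSE]
  rownames(ur) <- NULL
  args <- list(...)
  if (is.null(args$library_id))
    args$library_id <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq_path))
  do.call(read_library, c(list(unique_reads = ur), args))
}

#' Write reads as FASTQ (constant quality)
#'
#' @param seqs character vector of read sequences.
#' @param path output path.
#' @param id_prefix read-name prefix.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path, id_prefix = "read") {
  qual <- vapply(nchar(seqs), function(L)
    paste(rep("I", L), collapse = ""), character(1))
  rec <- paste0("@", id_prefix, "_", sprintf("%06d", seq_along(seqs)),
                "\n", seqs, "\n+\n", qual)
  writeLines(rec, path)
  invisible(path)
}

#' Read-length distribution of a library
#'
#' @param library a `ReadLibrary`.
#' @return data.frame with `length`, `total_count` (sums to
#'   `clean_size`) and `unique_count` (sums to the number of unique
#'   sequences), one row per observed length, ascending.
#' @export
length_distribution <- function(library) {
  stopifnot(inherits(library, "ReadLibrary"))
  ur <- library$unique_reads
  if (!nrow(ur))
    return(data.frame(length = integer(0), total_count = integer(0),
                      unique_count = integer(0)))
  L <- nchar(ur$seq)
  total <- tapply(ur$count, L, sum)
  uniq <- tapply(ur$count, L, length)
  data.frame(length = as.integer(names(total)),
             total_count = as.integer(total),
             unique_count = as.integer(uniq), row.names = NULL)
}

#' Read / write FASTA
#'
#' Thin wrappers around Biostrings keeping the package's plain
#' character representation.
#'
#' @param path file path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(normalize_dna(as.character(x), strict = FALSE), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Write / read a genome FASTA
#' @param genome a `Genome`.
#' @param path file path.
#' @export
write_genome_fasta <- function(genome, path) write_fasta(unclass(genome), path)

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) structure(read_fasta(path), class = "Genome")

#' Read / write MIRNA locus intervals as GFF3
#'
#' GFF3 on disk is 1-based inclusive (as is this package internally,
#' following the IRanges convention). Round-trip write -> read is the
#' identity on (name, chrom, start, end, strand).
#'
#' @param loci data.frame with columns `name`, `chrom`, `start`, `end`,
#'   `strand` (a `TruthSet`'s loci are converted with [loci_table()]).
#' @param path file path.
#' @param type GFF3 feature type.
#' @export
write_loci_gff3 <- function(loci, path, type = "miRNA_primary_transcript") {
  stopifnot(all(c("name", "chrom", "start", "end", "strand") %in% names(loci)))
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start, end = loci$end),
    strand = loci$strand)
  S4Vectors::mcols(gr)$ID <- loci$name
  S4Vectors::mcols(gr)$Name <- loci$name
  S4Vectors::mcols(gr)$type <- type
  S4Vectors::mcols(gr)$source <- "chalkmir"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_loci_gff3
#' @export
read_loci_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  nm <- S4Vectors::mcols(gr)$Name
  if (is.null(nm)) nm <- S4Vectors::mcols(gr)$ID
  data.frame(name = as.character(nm),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Flatten a TruthSet's loci to an interval table
#' @param truth a `TruthSet`.
#' @return data.frame with `name`, `chrom`, `start`, `end`, `strand`,
#'   `fold_change`.
#' @export
loci_table <- function(truth) {
  stopifnot(inherits(truth, "TruthSet"))
  do.call(rbind, lapply(truth$loci, function(l)
    data.frame(name = l$name, chrom = l$chrom, start = l$start,
               end = l$end, strand = l$strand,
               fold_change = l$fold_change, stringsAsFactors = FALSE)))
}

#' Read / write Vienna dot-bracket (.dbn) files
#'
#' Records of three lines: `>name`, sequence, structure. The structure
#' must be the same length as the sequence and have balanced brackets.
#'
#' @param path file path.
#' @return `read_dbn`: data.frame with `name`, `seq`, `structure`.
#' @export
read_dbn <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 3 != 0)
    stop("malformed .dbn file: expected 3-line records")
  n <- length(lines) %/% 3
  out <- data.frame(name = character(n), seq = character(n),
                    structure = character(n), stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    hdr <- lines[3 * k - 2]
    if (!startsWith(hdr, ">")) stop("malformed .dbn record ", k)
    out$name[k] <- sub("^>\\s*", "", hdr)
    out$seq[k] <- lines[3 * k - 1]
    out$structure[k] <- lines[3 * k]
    validate_structure(out$seq[k], out$structure[k])
  }
  out
}

#' @rdname read_dbn
#' @param records data.frame with `name`, `seq`, `structure`.
#' @export
write_dbn <- function(records, path) {
  for (k in seq_len(nrow(records)))
    validate_structure(records$seq[k], records$structure[k])
  writeLines(rbind(paste0(">", records$name), records$seq,
                   records$structure), path)
  invisible(path)
}

## dot-bracket sanity: length match, balanced brackets, only .()
validate_structure <- function(seq, structure) {
  if (nchar(structure) != nchar(seq))
    stop("structure length (", nchar(structure),
         ") != sequence length (", nchar(seq), ")")
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  if (!all(ch %in% c(".", "(", ")")))
    stop("structure contains characters outside .()")
  depth <- cumsum((ch == "(") - (ch == ")"))
  if (any(depth < 0) || (length(depth) && depth[length(depth)] != 0))
    stop("unbalanced brackets in structure")
  invisible(TRUE)
}

#' Convert between GFF3 (1-based inclusive) and 0-based half-open
#' coordinates
#'
#' Utilities for interoperating with 0-based tools; this package's own
#' internal convention is 1-based inclusive (the IRanges convention).
#'
#' @param start,end interval in the source convention.
#' @return two-element integer vector in the target convention.
#' @export
gff_to_zero_based <- function(start, end) c(start - 1L, end)

#' @rdname gff_to_zero_based
#' @export
zero_based_to_gff <- function(start, end) c(start + 1L, end)
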