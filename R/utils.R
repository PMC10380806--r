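## Internal helpers shared across modules.

#' @importFrom data.table data.table as.data.table rbindlist setkey
.datatable.aware <- TRUE

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the {A,C,G,T,N} alphabet.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(out, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

## Normalize a sequence to uppercase DNA (U -> T). Errors on anything
## outside the ACGTUN alphabet when strict.
normalize_dna <- function(x, strict = TRUE, allow_n = TRUE) {
  x <- chartr("u", "T", toupper(x))
  x <- chartr("U", "T", x)
  if (strict) {
    pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
    bad <- !grepl(pat, x)
    if (any(bad)) {
      stop("sequence contains non-ACGT(U/N) characters: ",
           substr(x[bad][1], 1, 40), call. = FALSE)
    }
  }
  x
}

## DNA -> RNA alphabet for user-facing miRNA sequence output.
to_rna <- function(x) chartr("Tt", "Uu", x)

## Deterministic child seed derivation, kept below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## mismatches between two equal-length strings (byte comparison)
hamming <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}
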