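## Fixture builders shared by the tests; everything is generated in
## code, nothing is read from disk.

## reverse complement independent of the package implementation
rc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))

## perfect-stem hairpin: arm + loop + revcomp(arm); returns hairpin
## string and arm coordinates
perfect_hairpin <- function(arm, loop = "AAAA") {
  hp <- paste0(arm, loop, rc(arm))
  list(hairpin = hp, arm_len = nchar(arm), n = nchar(hp),
       loop_len = nchar(loop))
}

## Build a synthetic duplex structure from interior-loop specs.
## `loops` is a list of c(gA, gB) gaps inserted between 4-bp paired
## blocks, walking from the duplex outside (A 5' end) inward. Returns
## hairpin sequence (N's), dot-bracket structure, and mature/star
## coordinates (with 2-nt 3' overhangs appended to both arms, outside
## the scored region). Expected counts under column-wise scoring:
## sum(max(gA,gB)) mismatches, sum(|gA-gB|) asymmetric-bulge nt.
duplex_case <- function(loops, block = 4L, loop_nt = 6L) {
  sA <- character(0); sB <- character(0)   # B built 3'->5', reversed later
  add_block <- function() {
    sA <<- c(sA, rep("(", block)); sB <<- c(sB, rep(")", block))
  }
  add_block()
  for (lp in loops) {
    sA <- c(sA, rep(".", lp[1]))
    sB <- c(sB, rep(".", lp[2]))
    add_block()
  }
  a_struct <- paste(sA, collapse = "")
  b_struct <- paste(rev(sB), collapse = "")
  # arms plus 2-nt 3' overhangs: A's overhang after its 3' end (facing
  # the loop), B's overhang at the hairpin 3' end
  a_full <- paste0(a_struct, "..")
  b_full <- paste0(b_struct, "..")
  structure_str <- paste0(a_full, paste(rep(".", loop_nt), collapse = ""),
                          b_full)
  n <- nchar(structure_str)
  la <- nchar(a_full); lb <- nchar(b_full)
  seq <- paste(rep("N", n), collapse = "")
  list(seq = seq, structure = structure_str,
       mature = c(1L, la),
       star = c(n - lb + 1L, n),
       expected_unpaired = sum(vapply(loops, max, numeric(1))),
       expected_asym = sum(vapply(loops, function(g) abs(g[1] - g[2]),
                                  numeric(1))))
}

## random DNA string
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

## write a FASTQ file from sequences (constant quality)
write_test_fastq <- function(seqs, path) {
  qual <- vapply(nchar(seqs), function(L)
    paste(rep("I", L), collapse = ""), character(1))
  writeLines(paste0("@r", seq_along(seqs), "\n", seqs, "\n+\n", qual),
             path)
  path
}

## tiny simulation design for fast tests; any default can be overridden
tiny_design <- function(...) {
  defaults <- list(genotypes = c("G1", "G2"), replicates_per_cell = 2L,
                   n_true_loci = 4L, n_background_clusters = 2L,
                   mean_locus_count = 80)
  do.call(sim_design, utils::modifyList(defaults, list(...)))
}
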