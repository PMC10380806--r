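## Synthetic-data module: toy genomes with planted MIRNA hairpins and
## simulated multi-genotype CDT/HDT small-RNA libraries with known truth.

#' Simulation design for synthetic sRNA libraries
#'
#' Describes the experimental design and generative parameters used by
#' [plant_mirna_loci()] and [simulate_libraries()]. Defaults emulate the
#' study design the package targets: 5 rice genotypes, control (CDT) vs
#' high daytime temperature (HDT), 3 replicates per cell, mature lengths
#' peaking at 21 nt with a secondary 24-nt class, high dicing precision,
#' and negative-binomial counts with log-normal library-size factors.
#'
#' @param genotypes character vector of genotype labels.
#' @param conditions length-2 character vector, `c(control, treatment)`.
#' @param replicates_per_cell replicates per genotype x condition cell.
#' @param n_true_loci number of MIRNA hairpins to plant.
#' @param n_background_clusters number of siRNA-like background
#'   clusters (24-nt biased, uniformly tiled reads; true negatives for
#'   the precision filter).
#' @param mature_length_weights named numeric, mature length (20-24 nt)
#'   to probability; must sum to 1.
#' @param dicing_precision probability that a locus read is exactly the
#'   mature or star sequence; otherwise its ends are shifted.
#' @param arm_bias probability a locus read comes from the mature arm.
#' @param mean_locus_count expected reads per locus per library before
#'   fold change and library-size factor.
#' @param dispersion negative-binomial dispersion phi >= 0
#'   (`var = mu + phi * mu^2`); 0 gives Poisson counts.
#' @param size_factor_sdlog sdlog of the log-normal library-size
#'   factors (0 disables them).
#' @param fold_changes named numeric, locus name to multiplicative
#'   treatment effect; loci absent from the map get 1.0.
#' @param seed integer seed; all randomness derives from it.
#' @return object of class `SimDesign` (a validated list).
#' @export
sim_design <- function(genotypes = c("Bengal", "Cypress", "Kaybonnet",
                                     "LaGrue", "Nipponbare"),
                       conditions = c("CDT", "HDT"),
                       replicates_per_cell = 3L,
                       n_true_loci = 30L,
                       n_background_clusters = 20L,
                       mature_length_weights = c(`20` = 0.05, `21` = 0.55,
                                                 `22` = 0.10, `23` = 0.10,
                                                 `24` = 0.20),
                       dicing_precision = 0.95,
                       arm_bias = 0.7,
                       mean_locus_count = 200,
                       dispersion = 0.1,
                       size_factor_sdlog = 0.2,
                       fold_changes = numeric(0),
                       seed = 1L) {
  stopifnot(length(conditions) == 2, length(genotypes) >= 1,
            replicates_per_cell >= 1, n_true_loci >= 0,
            n_background_clusters >= 0,
            dicing_precision >= 0, dicing_precision <= 1,
            arm_bias >= 0, arm_bias <= 1,
            mean_locus_count > 0, dispersion >= 0,
            size_factor_sdlog >= 0)
  lens <- as.integer(names(mature_length_weights))
  if (any(is.na(lens)) || any(lens < 20L) || any(lens > 24L))
    stop("mature_length_weights must be named by lengths in 20..24")
  if (abs(sum(mature_length_weights) - 1) > 1e-8)
    stop("mature_length_weights must sum to 1")
  structure(list(genotypes = genotypes,
                 conditions = conditions,
                 replicates_per_cell = as.integer(replicates_per_cell),
                 n_true_loci = as.integer(n_true_loci),
                 n_background_clusters = as.integer(n_background_clusters),
                 mature_length_weights = mature_length_weights,
                 dicing_precision = dicing_precision,
                 arm_bias = arm_bias,
                 mean_locus_count = mean_locus_count,
                 dispersion = dispersion,
                 size_factor_sdlog = size_factor_sdlog,
                 fold_changes = fold_changes,
                 seed = as.integer(seed)),
            class = "SimDesign")
}

#' Generate a random genome
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param chrom_length chromosome length in bp (>= 0; recycled).
#' @param gc_fraction expected GC content in `[0, 1]`.
#' @param seed integer seed; identical seeds give byte-identical genomes.
#' @return named character vector of class `Genome` (chr1, chr2, ...).
#' @export
make_genome <- function(n_chrom = 1L, chrom_length = 100000L,
                        gc_fraction = 0.44, seed = 1L) {
  if (n_chrom < 1) stop("n_chrom must be >= 1")
  if (any(chrom_length < 0)) stop("chrom_length must be >= 0")
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must be in [0,1]")
  chrom_length <- rep_len(as.integer(chrom_length), n_chrom)
  set.seed(as.integer(seed))
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seqs <- vapply(chrom_length, function(L) {
    if (L == 0) return("")
    paste(sample(DNA_BASES, L, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  structure(seqs, class = "Genome")
}

#' @export
print.Genome <- function(x, ...) {
  cat("Genome with", length(x), "chromosome(s):\n")
  for (nm in names(x)) cat(" ", nm, nchar(x[[nm]]), "bp\n")
  invisible(x)
}

## random DNA string, GC 0.5
random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

#' Construct a MIRNA locus object
#'
#' @param name locus name.
#' @param chrom,start,end,strand genomic placement (1-based inclusive).
#' @param hairpin precursor sequence (genomic plus strand for `+` loci,
#'   reverse complement for `-` loci; always written 5' to 3').
#' @param structure dot-bracket secondary structure of `hairpin`.
#' @param mature_5p,mature_3p lists with `seq`, `start`, `end`
#'   (hairpin-local, 1-based) for the 5p and 3p arms of the duplex.
#' @param mature_arm `"5p"` or `"3p"`: which arm is the designated
#'   mature miRNA (the other is the star).
#' @param fold_change simulated treatment effect (truth bookkeeping).
#' @param context optional list with `seq` and `offset`: plus-strand
#'   genomic sequence spanning the locus with a few nt of flank, so
#'   reads with shifted ends can be extracted without the genome.
#' @return object of class `MirnaLocus`.
#' @export
mirna_locus <- function(name, chrom, start, end, strand, hairpin,
                        structure = NULL, mature_5p, mature_3p,
                        mature_arm = "5p", fold_change = 1,
                        context = NULL) {
  stopifnot(strand %in% c("+", "-"), mature_arm %in% c("5p", "3p"))
  n <- nchar(hairpin)
  for (arm in list(mature_5p, mature_3p)) {
    stopifnot(arm$start >= 1, arm$end <= n,
              arm$end - arm$start + 1 == nchar(arm$seq))
  }
  if (mature_5p$end >= mature_3p$start)
    stop("5p and 3p arms overlap")
  structure(list(name = name, chrom = chrom, start = start, end = end,
                 strand = strand, hairpin = hairpin,
                 structure = structure,
                 mature_5p = mature_5p, mature_3p = mature_3p,
                 mature_arm = mature_arm, fold_change = fold_change,
                 context = context),
            class = "MirnaLocus")
}

## the designated mature / star arms of a locus
locus_mature <- function(locus)
  if (locus$mature_arm == "5p") locus$mature_5p else locus$mature_3p
locus_star <- function(locus)
  if (locus$mature_arm == "5p") locus$mature_3p else locus$mature_5p

## hairpin-local [start,end] -> genomic [start,end] (both 1-based)
locus_local_to_genomic <- function(locus, lstart, lend) {
  n <- nchar(locus$hairpin)
  if (locus$strand == "+") {
    c(locus$start + lstart - 1L, locus$start + lend - 1L)
  } else {
    c(locus$start + n - lend, locus$start + n - lstart)
  }
}

## Build one synthetic hairpin: fully paired stem of (2 + L + 2) bp
## around a random mature, random 8-12 nt loop. Mature/star carry 2-nt
## 3' overhangs by construction. At least 3 G:U wobble pairs are
## planted in the stem (real stems have them); they keep the duplex
## fully paired but break the exact reverse-complement palindromy that
## would otherwise let arm reads cross-map antisense to the opposite
## arm. Returns NULL when the random mature offers too few wobble
## sites (caller resamples).
build_hairpin <- function(mature_len, n_wobble = 3L) {
  f5 <- random_dna(2); f3 <- random_dna(2)
  mat <- random_dna(mature_len)
  arm <- paste0(f5, mat, f3)
  armB <- revcomp(arm)
  # wobble sites: armB positions holding C (pairing a G in the mature
  # core), away from the arm ends; C -> T turns G:C into a G:U pair
  w <- nchar(armB)
  cand <- which(strsplit(armB, "")[[1]] == "C")
  core <- cand[cand > 4 & cand < w - 4]
  if (length(core) < n_wobble) return(NULL)
  picks <- sort(sample(core, n_wobble))
  for (p in picks) substr(armB, p, p) <- "T"
  loop <- random_dna(sample(8:12, 1))
  hp <- paste0(arm, loop, armB)
  n <- nchar(hp)
  list(hairpin = hp,
       m5 = list(seq = mat, start = 3L, end = 2L + mature_len),
       m3 = list(seq = substr(hp, n - mature_len + 1L, n),
                 start = n - mature_len + 1L, end = n))
}

#' Plant MIRNA hairpins and background intervals into a genome
#'
#' Each planted hairpin has a perfect stem, so its mature/star duplex
#' passes [check_duplex()] by construction; this is verified by folding
#' each hairpin (loci whose random flanks or loop confuse the folder are
#' resampled). Background intervals are reserved, non-overlapping
#' stretches from which siRNA-like reads are later tiled.
#'
#' @param genome a `Genome` from [make_genome()].
#' @param design a `SimDesign`.
#' @return list with elements `genome` (hairpins written in) and
#'   `truth` (class `TruthSet`: `loci`, a list of `MirnaLocus`;
#'   `background`, a data.frame of intervals with their sequences).
#' @export
plant_mirna_loci <- function(genome, design) {
  stopifnot(inherits(genome, "Genome"), inherits(design, "SimDesign"))
  set.seed(derive_seed(design$seed, 1L))
  n_loci <- design$n_true_loci
  n_bg <- design$n_background_clusters
  if (n_loci == 0 && n_bg == 0)
    return(list(genome = genome,
                truth = structure(list(loci = list(),
                                       background = empty_background()),
                                  class = "TruthSet")))
  lens <- as.integer(names(design$mature_length_weights))
  mature_lens <- if (n_loci > 0)
    lens[sample.int(length(lens), n_loci, replace = TRUE,
                    prob = design$mature_length_weights)] else integer(0)
  bg_width <- 280L
  spacing <- 200L
  # unit widths: hairpin max width 2*(24+4)+12 = 68; reserve generously
  unit_w <- c(rep(80L, n_loci), rep(bg_width, n_bg))
  n_units <- length(unit_w)
  # assign units to chromosomes proportionally to length
  chrom_len <- nchar(unclass(genome))
  chrom_of <- sample(names(genome), n_units, replace = TRUE,
                     prob = chrom_len / sum(chrom_len))
  starts <- integer(n_units)
  for (chr in names(genome)) {
    idx <- which(chrom_of == chr)
    if (!length(idx)) next
    need <- sum(unit_w[idx] + spacing)
    if (need > chrom_len[[chr]])
      stop("insufficient genome space on ", chr, ": need ", need,
           " bp, have ", chrom_len[[chr]])
    slack <- chrom_len[[chr]] - need
    # random non-negative gaps summing to <= slack
    cuts <- sort(sample.int(slack + 1L, length(idx), replace = TRUE) - 1L)
    pos <- 1L
    for (k in seq_along(idx)) {
      gap <- cuts[k] - (if (k == 1) 0L else cuts[k - 1L])
      pos <- pos + gap + spacing %/% 2L
      starts[idx[k]] <- pos
      pos <- pos + unit_w[idx[k]] + spacing %/% 2L
    }
  }
  loci <- vector("list", n_loci)
  chroms <- unclass(genome)
  fc_map <- design$fold_changes
  for (i in seq_len(n_loci)) {
    nm <- sprintf("locus_%02d", i)
    strand <- sample(c("+", "-"), 1)
    for (attempt in 1:50) {
      hp <- build_hairpin(mature_lens[i])
      if (is.null(hp)) {
        if (attempt == 50) stop("could not build a passing hairpin for ", nm)
        next
      }
      fold <- fold_hairpin(hp$hairpin)
      rep5 <- check_duplex(hp$hairpin, fold,
                           mature = c(hp$m5$start, hp$m5$end),
                           star = c(hp$m3$start, hp$m3$end))
      if (rep5$passes) break
      if (attempt == 50) stop("could not build a passing hairpin for ", nm)
    }
    g1 <- starts[i]
    g2 <- g1 + nchar(hp$hairpin) - 1L
    chr <- chrom_of[i]
    insert <- if (strand == "+") hp$hairpin else revcomp(hp$hairpin)
    substr(chroms[[chr]], g1, g2) <- insert
    ctx_start <- max(1L, g1 - 5L)
    loci[[i]] <- mirna_locus(
      name = nm, chrom = chr, start = g1, end = g2, strand = strand,
      hairpin = hp$hairpin, structure = fold,
      mature_5p = hp$m5, mature_3p = hp$m3,
      mature_arm = sample(c("5p", "3p"), 1),
      fold_change = if (nm %in% names(fc_map)) unname(fc_map[[nm]]) else 1,
      context = NULL)
  }
  # context extraction after all insertions
  for (i in seq_len(n_loci)) {
    l <- loci[[i]]
    cs <- max(1L, l$start - 5L)
    ce <- min(nchar(chroms[[l$chrom]]), l$end + 5L)
    loci[[i]]$context <- list(seq = substr(chroms[[l$chrom]], cs, ce),
                              offset = cs)
  }
  bg <- if (n_bg > 0) {
    idx <- n_loci + seq_len(n_bg)
    data.frame(name = sprintf("bg_%02d", seq_len(n_bg)),
               chrom = chrom_of[idx], start = starts[idx],
               end = starts[idx] + bg_width - 1L,
               strand = sample(c("+", "-"), n_bg, replace = TRUE),
               stringsAsFactors = FALSE)
  } else empty_background()
  if (n_bg > 0)
    bg$seq <- vapply(seq_len(n_bg), function(k)
      substr(chroms[[bg$chrom[k]]], bg$start[k], bg$end[k]), character(1))
  out_genome <- structure(chroms, class = "Genome")
  truth <- structure(list(loci = loci, background = bg), class = "TruthSet")
  list(genome = out_genome, truth = truth)
}

empty_background <- function()
  data.frame(name = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             seq = character(0), stringsAsFactors = FALSE)

## Per-end dicing offset: -1/0/+1 equiprobable, 2-nt shifts at one
## tenth that rate (used only for the imprecise fraction of reads).
sample_end_shifts <- function(n) {
  sample(c(-2L, -1L, 0L, 1L, 2L), n, replace = TRUE,
         prob = c(0.1, 1, 1, 1, 0.1) / 3.2)
}

## NB draw honouring phi = 0 (Poisson limit)
rnb <- function(n, mu, phi) {
  if (phi <= 0) rpois(n, mu) else rnbinom(n, size = 1 / phi, mu = mu)
}

## Extract the read sequence for an arm of `locus` with 5'/3' end
## shifts d5/d3 (transcript orientation; negative = extend outward).
arm_read_seq <- function(locus, arm, d5, d3) {
  g <- locus_local_to_genomic(locus, arm$start, arm$end)
  if (locus$strand == "+") {
    gs <- g[1] + d5; ge <- g[2] + d3
  } else {
    gs <- g[1] - d3; ge <- g[2] - d5
  }
  off <- locus$context$offset
  s <- substr(locus$context$seq, gs - off + 1L, ge - off + 1L)
  if (locus$strand == "-") s <- revcomp(s)
  s
}

#' Simulate sRNA libraries from a planted truth set
#'
#' One library per genotype x condition x replicate. Per locus and
#' library, the read count is negative-binomial with mean
#' `mean_locus_count * fold_change (treatment only) * size_factor`,
#' where the library-size factor is log-normal (sdlog 0.2). A fraction
#' `dicing_precision` of locus reads are the exact mature or star
#' sequence (arm chosen by `arm_bias`); the rest have each end shifted
#' independently by -1/0/+1 nt (2-nt shifts at a tenth that rate).
#' Background clusters emit uniformly tiled reads with a 24-nt length
#' mode. Fully deterministic given `design$seed`.
#'
#' @param truth `TruthSet` from [plant_mirna_loci()].
#' @param design the same `SimDesign`.
#' @param out_dir if non-NULL, write one FASTQ per library here
#'   (constant quality `I`; the pipeline never uses base quality).
#' @return list of `ReadLibrary` objects; each carries a `provenance`
#'   attribute (data.frame of per-source read counts).
#' @export
simulate_libraries <- function(truth, design, out_dir = NULL) {
  stopifnot(inherits(truth, "TruthSet"), inherits(design, "SimDesign"))
  grid <- expand.grid(replicate = seq_len(design$replicates_per_cell),
                      condition = design$conditions,
                      genotype = design$genotypes,
                      stringsAsFactors = FALSE)
  libs <- vector("list", nrow(grid))
  bg_len_pool <- c(21L, 22L, 23L, 24L, 25L)
  bg_len_prob <- c(0.05, 0.05, 0.15, 0.60, 0.15)
  for (k in seq_len(nrow(grid))) {
    set.seed(derive_seed(design$seed, 1000L + k))
    size_factor <- if ((design$size_factor_sdlog %||% 0.2) > 0)
      rlnorm(1, 0, design$size_factor_sdlog) else 1
    is_trt <- grid$condition[k] == design$conditions[2]
    seqs <- character(0); src <- character(0)
    for (locus in truth$loci) {
      mu <- design$mean_locus_count * size_factor *
        (if (is_trt) locus$fold_change else 1)
      n <- rnb(1, mu, design$dispersion)
      if (n == 0) next
      from_mature <- runif(n) < design$arm_bias
      precise <- runif(n) < design$dicing_precision
      d5 <- ifelse(precise, 0L, sample_end_shifts(n))
      d3 <- ifelse(precise, 0L, sample_end_shifts(n))
      mat <- locus_mature(locus); star <- locus_star(locus)
      rs <- vapply(seq_len(n), function(j)
        arm_read_seq(locus, if (from_mature[j]) mat else star,
                     d5[j], d3[j]), character(1))
      seqs <- c(seqs, rs)
      src <- c(src, rep(locus$name, n))
    }
    if (nrow(truth$background)) {
      for (b in seq_len(nrow(truth$background))) {
        bgr <- truth$background[b, ]
        n <- rnb(1, design$mean_locus_count * size_factor,
                 design$dispersion)
        if (n == 0) next
        lens <- sample(bg_len_pool, n, replace = TRUE, prob = bg_len_prob)
        width <- bgr$end - bgr$start + 1L
        starts <- vapply(lens, function(L)
          sample.int(width - L + 1L, 1L), integer(1))
        rs <- substring(bgr$seq, starts, starts + lens - 1L)
        if (bgr$strand == "-") rs <- revcomp(rs)
        seqs <- c(seqs, rs)
        src <- c(src, rep(bgr$name, n))
      }
    }
    lib_id <- sprintf("%s_%s_r%d", grid$genotype[k], grid$condition[k],
                      grid$replicate[k])
    tab <- table(seqs)
    ur <- data.frame(seq = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
    ur <- ur[order(ur$seq), , drop = FALSE]
    rownames(ur) <- NULL
    lib <- read_library(lib_id, genotype = grid$genotype[k],
                        condition = grid$condition[k],
                        replicate = grid$replicate[k],
                        unique_reads = ur)
    prov <- as.data.frame(table(source = src), stringsAsFactors = FALSE)
    names(prov)[2] <- "count"
    attr(lib, "provenance") <- prov
    attr(lib, "size_factor") <- size_factor
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      write_fastq(seqs, file.path(out_dir, paste0(lib_id, ".fastq")),
                  id_prefix = lib_id)
    }
    libs[[k]] <- lib
  }
  names(libs) <- vapply(libs, function(l) l$library_id, character(1))
  libs
}
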