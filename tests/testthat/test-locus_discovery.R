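test_that("map_reads finds planted exact and 1-mismatch hits only", {
  set.seed(101)
  g <- make_genome(1, 5000, seed = 101)
  read <- substr(g[[1]], 1001, 1021)            # unique 21-mer
  lib <- data.frame(seq = read, count = 3L)
  aln <- map_reads(g, lib)
  expect_identical(nrow(aln), 1L)
  expect_identical(aln$start, 1001L)
  expect_identical(aln$n_mismatches, 0L)
  expect_identical(aln$count, 3L)

  # two substitutions: no alignment (one mismatch allowed for mapping)
  r2 <- read
  substr(r2, 3, 3) <- if (substr(r2, 3, 3) == "A") "C" else "A"
  substr(r2, 10, 10) <- if (substr(r2, 10, 10) == "G") "T" else "G"
  aln2 <- map_reads(g, data.frame(seq = r2, count = 1L))
  expect_identical(nrow(aln2), 0L)

  # one substitution: found with n_mismatches = 1
  r1 <- read
  substr(r1, 5, 5) <- if (substr(r1, 5, 5) == "A") "C" else "A"
  aln1 <- map_reads(g, data.frame(seq = r1, count = 1L))
  expect_true(any(aln1$start == 1001 & aln1$n_mismatches == 1))
})

test_that("map_reads equals the exhaustive oracle on a 10-kb genome", {
  g <- make_genome(1, 10000, seed = 7)
  set.seed(7)
  reads <- character(25)
  for (i in 1:25) {
    L <- sample(19:24, 1)
    s <- sample.int(10000 - L, 1)
    r <- substr(g[[1]], s, s + L - 1)
    # mix of exact, 1-mm, 2-mm and reverse-complement reads
    nmut <- sample(0:2, 1)
    for (m in seq_len(nmut)) {
      p <- sample.int(L, 1)
      substr(r, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(r, p, p)), 1)
    }
    if (runif(1) < 0.3) r <- rc(r)
    reads[i] <- r
  }
  reads <- unique(reads)
  lib <- data.frame(seq = reads, count = 1L)
  for (method in c("index", "scan")) {
    aln <- map_reads(g, lib, method = method)
    got <- aln[order(aln$seq, aln$chrom, aln$start, aln$strand),
               c("seq", "chrom", "start", "end", "strand", "n_mismatches")]
    rownames(got) <- NULL
    exp <- oracle_map_reads(g, reads)
    rownames(exp) <- NULL
    expect_identical(got, exp, label = method)
  }
})

test_that("map_reads validates inputs", {
  g0 <- structure(setNames("", "chr1"), class = "Genome")
  expect_error(map_reads(g0, data.frame(seq = "ACGTACGTACGTACGTACG",
                                        count = 1L)), "empty genome")
  g <- make_genome(1, 1000, seed = 1)
  # reads outside the 18-30 nt window never enter mapping
  aln <- map_reads(g, data.frame(seq = substr(g[[1]], 1, 10), count = 1L))
  expect_identical(nrow(aln), 0L)
})

test_that("call_clusters merges by gap and applies min_reads", {
  expect_identical(call_clusters(data.frame(seq = character(0),
                                            count = integer(0),
                                            chrom = character(0),
                                            start = integer(0),
                                            end = integer(0),
                                            strand = character(0),
                                            n_mismatches = integer(0))),
                   list())
  mk <- function(start, seq, count) data.frame(
    seq = seq, count = count, chrom = "chr1", start = start,
    end = start + nchar(seq) - 1L, strand = "+", n_mismatches = 0L,
    stringsAsFactors = FALSE)
  a <- rbind(mk(100L, "AAAAAAAAAAAAAAAAAAAAA", 20L),
             mk(600L, "CCCCCCCCCCCCCCCCCCCCC", 15L))
  cl_small <- call_clusters(a, min_reads = 10, max_gap = 100)
  expect_length(cl_small, 2L)
  cl_big <- call_clusters(a, min_reads = 10, max_gap = 600)
  expect_length(cl_big, 1L)
  expect_identical(cl_big[[1]]$total_count, 35L)
  # below min_reads: dropped
  expect_length(call_clusters(mk(5L, "GGGGGGGGGGGGGGGGGGGGG", 9L),
                              min_reads = 10), 0L)
  # most-abundant tie: lexicographically smaller sequence wins
  tie <- rbind(mk(100L, "TTTTTTTTTTTTTTTTTTTTT", 10L),
               mk(105L, "AAAAAAAAAAAAAAAAAAAAA", 10L))
  expect_identical(call_clusters(tie, min_reads = 5)[[1]]$mature_seq,
                   "AAAAAAAAAAAAAAAAAAAAA")
})

test_that("call_clusters is order-invariant and strand-aware", {
  set.seed(11)
  n <- 60
  a <- data.frame(seq = vapply(1:n, function(i) rand_seq(21),
                               character(1)),
                  count = sample(1:20, n, TRUE), chrom = "chr1",
                  start = sample.int(5000, n), strand =
                    sample(c("+", "-"), n, TRUE),
                  n_mismatches = 0L, stringsAsFactors = FALSE)
  a$end <- a$start + 20L
  c1 <- call_clusters(a, min_reads = 1, max_gap = 50)
  c2 <- call_clusters(a[sample.int(n), ], min_reads = 1, max_gap = 50)
  key <- function(cl) sort(vapply(cl, function(x)
    paste(x$chrom, x$start, x$end, x$strand, x$total_count,
          x$mature_seq), character(1)))
  expect_identical(key(c1), key(c2))
  # idempotence: calling on a single cluster's own alignments returns it
  one <- c1[[1]]
  again <- call_clusters(one$alignments, min_reads = 1, max_gap = 50)
  expect_length(again, 1L)
  expect_identical(again[[1]]$start, one$start)
  # opposite strands never merge
  b <- rbind(a[1, ], a[1, ])
  b$strand <- c("+", "-"); b$seq[2] <- rc(b$seq[2])
  expect_length(call_clusters(b, min_reads = 1, max_gap = 50), 2L)
})

test_that("intersect_known partitions by the 1-bp overlap rule", {
  mk_cand <- function(chrom, start, end, strand = "+") structure(
    list(chrom = chrom, start = start, end = end, strand = strand,
         total_count = 50L, mature_seq = "A", mature_start = start,
         mature_end = end, alignments = NULL), class = "CandidateLocus")
  cands <- list(mk_cand("chr1", 100L, 120L), mk_cand("chr1", 300L, 320L))
  # empty known set: everything novel
  part0 <- intersect_known(cands, NULL)
  expect_length(part0$novel, 2L)
  # 1-bp overlap at the boundary counts ([100,120] vs [120,140])
  known <- data.frame(chrom = "chr1", start = 120L, end = 140L,
                      strand = "+", stringsAsFactors = FALSE)
  part <- intersect_known(cands, known)
  expect_length(part$known_overlapping, 1L)
  expect_identical(part$known_overlapping[[1]]$start, 100L)
  # adjacent but not overlapping ([300,320] vs [321,330])
  known2 <- data.frame(chrom = "chr1", start = 321L, end = 330L,
                       strand = "+", stringsAsFactors = FALSE)
  expect_length(intersect_known(cands, known2)$novel, 2L)
  # opposite strand still overlaps by default, not when stranded
  known3 <- data.frame(chrom = "chr1", start = 110L, end = 115L,
                       strand = "-", stringsAsFactors = FALSE)
  expect_length(intersect_known(cands, known3)$known_overlapping, 1L)
  expect_length(intersect_known(cands, known3,
                                stranded = TRUE)$known_overlapping, 0L)
  # chromosome name mismatch warns and treats as non-overlapping
  known4 <- data.frame(chrom = "chrX", start = 100L, end = 120L,
                       strand = "+", stringsAsFactors = FALSE)
  expect_warning(p4 <- intersect_known(cands, known4), "absent")
  expect_length(p4$novel, 2L)
})

test_that("intersect_known matches the quadratic oracle on random sets", {
  set.seed(23)
  mk_cand <- function(chrom, start, end, strand) structure(
    list(chrom = chrom, start = start, end = end, strand = strand,
         total_count = 1L, mature_seq = "A", mature_start = start,
         mature_end = end, alignments = NULL), class = "CandidateLocus")
  cand_df <- data.frame(chrom = sample(c("chr1", "chr2"), 50, TRUE),
                        start = sample.int(2000, 50),
                        strand = sample(c("+", "-"), 50, TRUE),
                        stringsAsFactors = FALSE)
  cand_df$end <- cand_df$start + sample(20:80, 50, TRUE)
  known <- data.frame(chrom = sample(c("chr1", "chr2"), 50, TRUE),
                      start = sample.int(2000, 50),
                      strand = sample(c("+", "-"), 50, TRUE),
                      stringsAsFactors = FALSE)
  known$end <- known$start + sample(20:80, 50, TRUE)
  cands <- lapply(seq_len(50), function(i)
    mk_cand(cand_df$chrom[i], cand_df$start[i], cand_df$end[i],
            cand_df$strand[i]))
  for (stranded in c(FALSE, TRUE)) {
    part <- intersect_known(cands, known, stranded = stranded)
    hit <- oracle_overlaps(cand_df, known, stranded = stranded)
    expect_identical(length(part$known_overlapping), sum(hit))
    got_novel <- vapply(part$novel, `[[`, numeric(1), "start")
    expect_setequal(got_novel, cand_df$start[!hit])
  }
})

test_that("every planted locus with enough reads appears as a candidate", {
  g <- make_genome(1, 40000, seed = 41)
  d <- tiny_design(seed = 41)
  pl <- plant_mirna_loci(g, d)
  libs <- simulate_libraries(pl$truth, d)
  idx <- genome_index(pl$genome, 18:30)
  aln <- do.call(rbind, lapply(libs, function(l)
    map_reads(pl$genome, l, index = idx)))
  cl <- call_clusters(aln, min_reads = 10, max_gap = 75)
  tt <- loci_table(pl$truth)
  for (i in seq_len(nrow(tt))) {
    hit <- any(vapply(cl, function(x)
      x$chrom == tt$chrom[i] & x$start <= tt$end[i] &
        x$end >= tt$start[i], logical(1)))
    expect_true(hit, label = tt$name[i])
  }
})
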