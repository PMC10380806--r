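test_that("exact_test null identity and antisymmetry", {
  cnt <- matrix(c(10, 12, 11, 10, 12, 11), nrow = 1)
  g <- c("A", "A", "A", "B", "B", "B")
  r <- exact_test(cnt, g, phi = 0.1)
  expect_identical(r$log2FC, 0)
  expect_identical(r$p_value, 1)
  expect_identical(r$direction, "ns")
  # swapping group labels negates log2FC, preserves p
  set.seed(5)
  cnt2 <- matrix(rnbinom(60, size = 10, mu = 50), nrow = 10)
  g2 <- rep(c("A", "B"), each = 3)
  ra <- exact_test(cnt2, g2, phi = 0.1)
  rb <- exact_test(cnt2, rev(g2), phi = 0.1)
  expect_equal(ra$p_value, rb$p_value)
  expect_equal(ra$log2FC, -rb$log2FC)
  # both groups all-zero
  r0 <- exact_test(matrix(0, 1, 6), g2, phi = 0.1)
  expect_identical(r0$p_value, 1)
  expect_identical(r0$log2FC, 0)
})

test_that("exact-test p matches the enumeration oracle for totals <= 60", {
  set.seed(9)
  for (i in 1:200) {
    t <- sample(0:60, 1)
    kA <- sample(0:t, 1)
    phi <- sample(c(0, 0.05, 0.1, 0.3, 1), 1)
    nA <- sample(2:4, 1); nB <- sample(2:4, 1)
    got <- chalkmir:::exact_nb_pvalue(kA, t - kA, nA, nB, phi)
    exp <- oracle_exact_pvalue(kA, t - kA, nA, nB, phi)
    expect_equal(got, exp, tolerance = 1e-9,
                 label = sprintf("t=%d kA=%d phi=%.2f", t, kA, phi))
  }
})

test_that("exact_test respects unequal library sizes", {
  # same underlying concentration, 2x library size in group B
  cnt <- matrix(c(50, 52, 48, 100, 104, 96), nrow = 1)
  sizes <- c(1e6, 1e6, 1e6, 2e6, 2e6, 2e6)
  r <- exact_test(cnt, rep(c("A", "B"), each = 3), phi = 0.05,
                  clean_sizes = sizes)
  expect_gt(r$p_value, 0.5)
  expect_lt(abs(r$log2FC), 0.1)
})

test_that("common dispersion is recovered from simulated counts", {
  set.seed(31)
  n <- 2000
  # phi = 0.2, two groups of 3
  y <- cbind(matrix(rnbinom(3 * n, size = 5, mu = 100), ncol = 3),
             matrix(rnbinom(3 * n, size = 5, mu = 100), ncol = 3))
  grp <- rep(c("A", "B"), each = 3)
  est <- estimate_common_dispersion(y, grp)
  expect_gte(est$phi, 0.15)
  expect_lte(est$phi, 0.25)
  # Poisson data: phi below 0.02
  yp <- matrix(rpois(6 * n, 100), ncol = 6)
  estp <- estimate_common_dispersion(yp, grp)
  expect_lt(estp$phi, 0.02)
  # all-zero matrix
  expect_warning(z <- estimate_common_dispersion(matrix(0, 5, 6), grp),
                 "all-zero")
  expect_identical(z$phi, 0)
})

test_that("dispersion optimum matches a 500-point grid search", {
  set.seed(41)
  y <- cbind(matrix(rnbinom(3 * 300, size = 10, mu = 80), ncol = 3),
             matrix(rnbinom(3 * 300, size = 10, mu = 80), ncol = 3))
  grp <- rep(c("A", "B"), each = 3)
  est <- estimate_common_dispersion(y, grp)
  grid <- exp(seq(log(1e-4), log(2), length.out = 500))
  ll <- vapply(grid, function(phi)
    chalkmir:::cml_loglik(chalkmir:::equalize_counts(y, rep(1, 6)),
                          factor(grp), c("A", "B"), phi), numeric(1))
  phi_grid <- grid[which.max(ll)]
  # agreement within grid resolution (log-step ~ 2%)
  expect_lt(abs(log(est$phi) - log(phi_grid)), log(grid[2] / grid[1]) * 2)
})

test_that("interaction_test calibrates under the null and detects effects", {
  set.seed(51)
  geno <- rep(c("g1", "g2"), each = 6)
  cond <- rep(rep(c("CDT", "HDT"), each = 3), 2)
  phi <- 0.1
  # null: genotype and condition main effects only
  n_null <- 400
  mu <- outer(rep(1, n_null),
              ifelse(geno == "g2", 1.5, 1) * ifelse(cond == "HDT", 2, 1) * 100)
  y <- matrix(rnbinom(length(mu), size = 1 / phi, mu = mu), nrow = n_null)
  r <- interaction_test(y, geno, cond, phi = phi)
  rej <- mean(r$p_value < 0.05, na.rm = TRUE)
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.08)
  # planted interaction: 4x response in g1, 1x in g2, at the
  # stated-world locus mean (200); true power here is ~0.96, so this
  # smaller-n smoke check uses a 3-sigma-lower bound (the full-power
  # assertion lives in the acceptance suite)
  n_alt <- 200
  mu2 <- outer(rep(1, n_alt),
               200 * ifelse(cond == "HDT" & geno == "g1", 4, 1))
  y2 <- matrix(rnbinom(length(mu2), size = 1 / phi, mu = mu2), nrow = n_alt)
  r2 <- interaction_test(y2, geno, cond, phi = phi)
  expect_gte(mean(r2$p_value < 0.05, na.rm = TRUE), 0.92)
  # all-zero row: p = 1
  r0 <- interaction_test(matrix(0, 1, 12), geno, cond, phi = phi)
  expect_identical(r0$p_value, 1)
})

test_that("interaction coefficient matches a brute-force grid fit", {
  # tiny 2x2 design with 2 replicates per cell
  geno <- rep(c("g1", "g2"), each = 4)
  cond <- rep(rep(c("C", "H"), each = 2), 2)
  y <- c(20, 24, 80, 90, 30, 28, 33, 35)
  phi <- 0.1
  r <- interaction_test(matrix(y, nrow = 1), geno, cond, phi = phi)
  # brute-force: maximize the NB likelihood over the saturated cell
  # means; the interaction log2FC is the log-ratio of response ratios
  cells <- interaction(geno, cond)
  ll_cell <- function(mu, yy) sum(dnbinom(yy, size = 1 / phi, mu = mu,
                                          log = TRUE))
  mu_hat <- vapply(levels(cells), function(cl) {
    yy <- y[cells == cl]
    optimize(ll_cell, c(1, 200), yy = yy, maximum = TRUE)$maximum
  }, numeric(1))
  # cells are ordered g1.C, g2.C, g1.H, g2.H
  expected_lfc <- log2((mu_hat["g1.H"] / mu_hat["g1.C"]) /
                         (mu_hat["g2.H"] / mu_hat["g2.C"]))
  # model.matrix interaction coefficient is genotype2:conditionH, i.e.
  # the g2-vs-g1 difference of responses: negate
  expect_equal(unname(r$log2FC), -unname(expected_lfc), tolerance = 1e-3)
})

test_that("compare_sets reproduces constructed memberships", {
  genos <- c("Bengal", "Cypress", "Kaybonnet", "LaGrue", "Nipponbare")
  mirnas <- sprintf("mir%02d", 1:20)
  tables <- lapply(genos, function(g) {
    d <- data.frame(miRNA = mirnas, contrast = "HDT_vs_CDT",
                    log2FC = 0, p_value = 1, direction = "ns",
                    stringsAsFactors = FALSE)
    d
  })
  names(tables) <- genos
  # mir01, mir02 up in all five; mir03 up only in Cypress;
  # mir04 up in both high-chalky and no low-chalky genotype
  groups <- list(high = c("LaGrue", "Nipponbare"),
                 low = c("Bengal", "Cypress", "Kaybonnet"))
  for (g in genos) {
    tables[[g]]$direction[1:2] <- "up"
  }
  tables$Cypress$direction[3] <- "up"
  for (g in groups$high) tables[[g]]$direction[4] <- "up"
  # mir05 down in all
  for (g in genos) tables[[g]]$direction[5] <- "down"
  sc <- compare_sets(tables, groups = groups)
  expect_setequal(sc$shared_up, c("mir01", "mir02"))
  expect_identical(unname(sc$counts["shared_up"]), 2L)
  expect_setequal(sc$shared_down, "mir05")
  expect_setequal(sc$specific_up$Cypress, "mir03")
  expect_setequal(sc$exclusive$up$high, "mir04")
  expect_length(sc$exclusive$up$low, 0)
  # brute-force oracle over the membership matrix
  o <- oracle_set_counts(sc$membership_up)
  expect_identical(length(sc$shared_up), o$shared)
  expect_identical(unname(lengths(sc$specific_up)),
                   as.integer(o$specific))
  # one empty table: shared sets empty
  tables$Bengal$direction[] <- "ns"
  sc2 <- compare_sets(tables, groups = groups)
  expect_length(sc2$shared_up, 0)
})

test_that("compare_sets matches brute force on random memberships", {
  set.seed(71)
  genos <- paste0("g", 1:5)
  mirnas <- sprintf("m%03d", 1:100)
  for (rep in 1:5) {
    tables <- lapply(genos, function(g) {
      dirs <- sample(c("up", "down", "ns"), 100, TRUE,
                     prob = c(0.2, 0.2, 0.6))
      data.frame(miRNA = mirnas, contrast = "c", log2FC = 0,
                 p_value = 1, direction = dirs, stringsAsFactors = FALSE)
    })
    names(tables) <- genos
    sc <- compare_sets(tables)
    for (m in list(sc$membership_up, sc$membership_down)) {
      o <- oracle_set_counts(m)
      expect_identical(sum(rowSums(m) == 5), o$shared)
    }
    # a miRNA is never both up and down in one genotype
    expect_false(any(sc$membership_up & sc$membership_down))
  }
})

test_that("direction calls obey the DEResult invariants", {
  set.seed(81)
  cnt <- matrix(rnbinom(600, size = 10, mu = 60), nrow = 100)
  cnt[1:30, 4:6] <- rnbinom(90, size = 10, mu = 240)
  g <- rep(c("A", "B"), each = 3)
  r <- exact_test(cnt, g, phi = 0.1)
  expect_true(all(r$p_value >= 0 & r$p_value <= 1))
  up <- r$direction == "up"
  expect_true(all(r$p_value[up] < 0.05 & r$log2FC[up] > 0))
  dn <- r$direction == "down"
  expect_true(all(r$p_value[dn] < 0.05 & r$log2FC[dn] < 0))
})
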