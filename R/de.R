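## Negative-binomial differential expression: common-dispersion
## estimation by conditional maximum likelihood, the two-group exact
## test conditioned on the per-feature total, a genotype-by-treatment
## interaction likelihood-ratio test, and shared/genotype-specific set
## comparison.

## Library-size equalization: rescale counts to the geometric mean of
## the clean library sizes (pseudo-counts; kept continuous for
## likelihood work, rounded only where integer totals are required).
equalize_counts <- function(counts, clean_sizes) {
  counts <- as.matrix(counts)
  stopifnot(length(clean_sizes) == ncol(counts), all(clean_sizes > 0))
  common <- exp(mean(log(clean_sizes)))
  sweep(counts, 2, clean_sizes, function(cnt, s) cnt * common / s)
}

#' Estimate a common negative-binomial dispersion
#'
#' Maximizes the conditional log-likelihood of the dispersion given
#' the per-group totals of library-size-equalized pseudo-counts,
#' summed over all features and groups, searched on the log scale.
#' `phi = 0` (the Poisson limit) is returned when the optimum sits at
#' the lower boundary.
#'
#' @param counts features x libraries matrix of raw counts.
#' @param group factor/vector of group labels (>= 2 libraries per
#'   group used).
#' @param clean_sizes per-library clean totals; equal sizes assumed
#'   when `NULL`.
#' @param interval log-scale search interval for phi.
#' @return list of class `DispersionEstimate`: `phi`, `method`.
#' @export
estimate_common_dispersion <- function(counts, group, clean_sizes = NULL,
                                       interval = c(1e-6, 5)) {
  counts <- as.matrix(counts)
  group <- as.factor(group)
  clean_sizes <- clean_sizes %||% rep(1, ncol(counts))
  if (all(counts == 0)) {
    warning("all-zero count matrix; dispersion set to 0")
    return(structure(list(phi = 0, method = "CML"),
                     class = "DispersionEstimate"))
  }
  pseudo <- equalize_counts(counts, clean_sizes)
  keep_groups <- names(which(table(group) >= 2))
  if (!length(keep_groups)) stop("need >= 2 libraries in some group")
  obj <- function(logphi) cml_loglik(pseudo, group, keep_groups,
                                     exp(logphi))
  opt <- optimize(obj, interval = log(interval), maximum = TRUE,
                  tol = 1e-6)
  phi <- exp(opt$maximum)
  # boundary -> Poisson
  if (opt$maximum <= log(interval[1]) + 1e-3 ||
      obj(log(interval[1])) >= opt$objective) phi <- interval[1]
  structure(list(phi = phi, method = "CML"),
            class = "DispersionEstimate")
}

## conditional log-likelihood of phi given group sums (y! terms
## dropped; they do not involve phi)
cml_loglik <- function(pseudo, group, keep_groups, phi) {
  r <- 1 / phi
  ll <- 0
  for (g in keep_groups) {
    y <- pseudo[, group == g, drop = FALSE]
    n <- ncol(y)
    ll <- ll + sum(lgamma(y + r)) - nrow(y) * n * lgamma(r) +
      nrow(y) * lgamma(n * r) - sum(lgamma(rowSums(y) + n * r))
  }
  ll
}

#' @export
print.DispersionEstimate <- function(x, ...) {
  cat("Common NB dispersion (", x$method, "): phi =",
      format(x$phi, digits = 4), "\n")
  invisible(x)
}

## conditional two-sided exact p for integer group sums kA, kB of nA
## and nB NB(mu, phi) libraries, given the total t = kA + kB:
## sum of probabilities of outcomes no more likely than observed
exact_nb_pvalue <- function(kA, kB, nA, nB, phi) {
  t <- kA + kB
  if (t == 0) return(1)
  k <- 0:t
  if (phi <= 0) {
    logw <- k * log(nA) + (t - k) * log(nB) -
      lgamma(k + 1) - lgamma(t - k + 1)
  } else {
    rA <- nA / phi; rB <- nB / phi
    logw <- lgamma(k + rA) - lgamma(k + 1) +
      lgamma(t - k + rB) - lgamma(t - k + 1)
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  obs <- w[kA + 1]
  min(1, sum(w[w <= obs * (1 + 1e-10)]))
}

#' Two-group negative-binomial exact test
#'
#' Counts are rescaled to a common library size; per feature, the
#' rounded group sums are compared with the conditional exact test
#' given the total (two-sided p: the sum of probabilities of all
#' outcomes no more likely than the observed one). The log2 fold
#' change uses per-library pseudo-count means with a prior count.
#'
#' @param counts vector (one feature) or features x libraries matrix.
#' @param group two-level factor/vector over libraries; the contrast
#'   is `second level vs first level`.
#' @param phi common NB dispersion (see
#'   [estimate_common_dispersion()]); 0 gives the Poisson/binomial
#'   limit.
#' @param clean_sizes per-library clean totals (equal when `NULL`).
#' @param prior_count prior added to rescaled group means in the
#'   log2FC.
#' @param alpha significance cutoff for the `direction` call.
#' @param contrast label stored in the result.
#' @return data.frame of class `DEResult`: `miRNA`, `contrast`,
#'   `log2FC`, `p_value`, `direction` (`up`/`down`/`ns`).
#' @export
exact_test <- function(counts, group, phi, clean_sizes = NULL,
                       prior_count = 0.5, alpha = 0.05,
                       contrast = NULL) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  counts <- as.matrix(counts)
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("group must have exactly 2 levels")
  lv <- levels(group)
  contrast <- contrast %||% paste0(lv[2], "_vs_", lv[1])
  clean_sizes <- clean_sizes %||% rep(1, ncol(counts))
  pseudo <- equalize_counts(counts, clean_sizes)
  iB <- group == lv[1]; iA <- group == lv[2]   # A = second level
  nA <- sum(iA); nB <- sum(iB)
  if (nA == 0 || nB == 0) stop("both groups need libraries")
  kA <- round(rowSums(pseudo[, iA, drop = FALSE]))
  kB <- round(rowSums(pseudo[, iB, drop = FALSE]))
  p <- vapply(seq_len(nrow(pseudo)), function(i)
    exact_nb_pvalue(kA[i], kB[i], nA, nB, phi), numeric(1))
  mA <- rowMeans(pseudo[, iA, drop = FALSE])
  mB <- rowMeans(pseudo[, iB, drop = FALSE])
  lfc <- log2((mA + prior_count) / (mB + prior_count))
  nm <- rownames(counts) %||% paste0("feature_", seq_len(nrow(counts)))
  de_result(nm, contrast, lfc, p, alpha)
}

de_result <- function(miRNA, contrast, log2FC, p_value, alpha = 0.05) {
  direction <- ifelse(is.na(p_value) | p_value >= alpha | log2FC == 0,
                      "ns", ifelse(log2FC > 0, "up", "down"))
  out <- data.frame(miRNA = miRNA, contrast = contrast, log2FC = log2FC,
                    p_value = p_value, direction = direction,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("DEResult", class(out))
  out
}

## NB log-likelihood with fixed phi (Poisson when phi <= 0)
nb_loglik <- function(y, mu, phi) {
  if (phi <= 0) sum(stats::dpois(y, mu, log = TRUE))
  else sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

## NB log-linear model with log link, offset, and fixed dispersion,
## fitted by iteratively reweighted least squares
nb_glm_fit <- function(y, X, offset, phi, maxit = 50L, tol = 1e-10) {
  beta <- tryCatch(qr.solve(X, log(y + 0.5) - offset),
                   error = function(e) rep(0, ncol(X)))
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    mu <- pmax(exp(eta), 1e-10)
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    sw <- sqrt(w)
    beta_new <- tryCatch(qr.solve(X * sw, z * sw),
                         error = function(e) beta)
    step <- beta_new - beta
    beta <- beta_new
    mu <- pmax(exp(drop(X %*% beta) + offset), 1e-10)
    ll <- nb_loglik(y, mu, phi)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(coef = beta, loglik = ll_old, converged = converged)
}

#' Genotype-by-treatment interaction test
#'
#' For each feature, fits the NB log-linear model
#' `~ genotype + condition + genotype:condition` with offsets
#' `log(clean_sizes)` and fixed dispersion, against the reduced model
#' without the interaction, and reports the likelihood-ratio p-value
#' (chi-square, 1 df) and the interaction coefficient as a log2 fold
#' change (the difference of the two genotypes' treatment responses).
#'
#' @param counts vector or features x libraries matrix.
#' @param genotype,condition two-level factors over libraries (2x2
#'   design with replicates).
#' @param phi common NB dispersion.
#' @param clean_sizes per-library clean totals (equal when `NULL`).
#' @param alpha significance cutoff for the direction call.
#' @return `DEResult` data.frame; non-converged rows have `p_value`
#'   `NA`.
#' @export
interaction_test <- function(counts, genotype, condition, phi,
                             clean_sizes = NULL, alpha = 0.05) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  counts <- as.matrix(counts)
  genotype <- as.factor(genotype)
  condition <- as.factor(condition)
  if (nlevels(genotype) != 2 || nlevels(condition) != 2)
    stop("interaction_test expects a 2x2 design")
  if (any(table(genotype, condition) < 1))
    stop("every genotype x condition cell needs libraries")
  clean_sizes <- clean_sizes %||% rep(1, ncol(counts))
  offset <- log(clean_sizes / exp(mean(log(clean_sizes))))
  Xf <- stats::model.matrix(~ genotype * condition)
  Xr <- stats::model.matrix(~ genotype + condition)
  n <- nrow(counts)
  lfc <- numeric(n); p <- numeric(n)
  for (i in seq_len(n)) {
    y <- counts[i, ]
    if (all(y == 0)) { lfc[i] <- 0; p[i] <- 1; next }
    full <- nb_glm_fit(y, Xf, offset, phi)
    red <- nb_glm_fit(y, Xr, offset, phi)
    if (!full$converged || !red$converged) {
      lfc[i] <- NA_real_; p[i] <- NA_real_; next
    }
    lrt <- max(0, 2 * (full$loglik - red$loglik))
    p[i] <- pchisq(lrt, df = 1, lower.tail = FALSE)
    lfc[i] <- full$coef[4] / log(2)
  }
  nm <- rownames(counts) %||% paste0("feature_", seq_len(n))
  de_result(nm, paste0("interaction_",
                       levels(genotype)[2], "x", levels(condition)[2]),
            lfc, p, alpha)
}

#' Compare differential-expression calls across genotypes
#'
#' Builds per-miRNA up/down membership over genotypes and derives the
#' Venn-style groups: miRNAs regulated in all genotypes, regulated in
#' every member of one chalkiness group and no member of the other,
#' and genotype-specific regulation (one genotype only).
#'
#' @param de_tables named list of `DEResult` tables, one per genotype,
#'   over the same miRNA universe (mismatched universes are
#'   intersected with a warning).
#' @param groups list with character vectors `high` and `low` naming
#'   the high- and low-chalkiness genotypes (optional; exclusive sets
#'   are skipped when absent).
#' @return object of class `SetComparison`: membership matrices and
#'   the derived sets with their counts.
#' @export
compare_sets <- function(de_tables, groups = NULL) {
  stopifnot(is.list(de_tables), !is.null(names(de_tables)))
  genos <- names(de_tables)
  universes <- lapply(de_tables, function(d) d$miRNA)
  universe <- Reduce(intersect, universes)
  if (!all(lengths(universes) == length(universe)))
    warning("mismatched miRNA universes; intersecting")
  up <- sapply(de_tables, function(d)
    d$direction[match(universe, d$miRNA)] == "up")
  down <- sapply(de_tables, function(d)
    d$direction[match(universe, d$miRNA)] == "down")
  if (length(universe) == 1) {
    up <- matrix(up, nrow = 1); down <- matrix(down, nrow = 1)
    colnames(up) <- colnames(down) <- genos
  }
  rownames(up) <- rownames(down) <- universe
  shared <- function(m) universe[rowSums(m) == ncol(m)]
  specific <- function(m) lapply(setNames(genos, genos), function(g)
    universe[m[, g] & rowSums(m) == 1])
  exclusive <- function(m, inside, outside)
    universe[rowSums(m[, inside, drop = FALSE]) == length(inside) &
             rowSums(m[, outside, drop = FALSE]) == 0]
  out <- list(membership_up = up, membership_down = down,
              shared_up = shared(up), shared_down = shared(down),
              specific_up = specific(up), specific_down = specific(down))
  if (!is.null(groups)) {
    stopifnot(all(c(groups$high, groups$low) %in% genos))
    out$exclusive <- list(
      up = list(high = exclusive(up, groups$high, groups$low),
                low = exclusive(up, groups$low, groups$high)),
      down = list(high = exclusive(down, groups$high, groups$low),
                  low = exclusive(down, groups$low, groups$high)))
  }
  out$counts <- c(shared_up = length(out$shared_up),
                  shared_down = length(out$shared_down),
                  specific_up = sum(lengths(out$specific_up)),
                  specific_down = sum(lengths(out$specific_down)))
  structure(out, class = "SetComparison")
}

#' @export
print.SetComparison <- function(x, ...) {
  cat("SetComparison over", ncol(x$membership_up), "genotypes,",
      nrow(x$membership_up), "miRNAs\n")
  print(x$counts)
  invisible(x)
}
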