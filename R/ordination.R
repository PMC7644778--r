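#' Compositional matrix for ordination
#'
#' Converts a family abundance table into the samples x families matrix used
#' for PCA: percent composition is computed on the full table, the table is
#' restricted to the `top_n` families, zeros are replaced by `zero_sub`
#' (percent units, so the default floor is log10(0.001) = -3), and log10 is
#' applied.
#'
#' @param family_table families x samples matrix of non-negative abundances.
#' @param top_n Number of families retained (ranked by overall abundance).
#' @param zero_sub Replacement for zero percentages, percent units.
#' @return samples x families matrix of log10 percent composition, with
#'   attributes `families` (the top-n list) and `zero_sub`.
#' @export
composition_matrix <- function(family_table, top_n = 100, zero_sub = 0.001) {
  totals <- colSums(family_table)
  drop <- totals == 0
  if (any(drop)) {
    warning("composition_matrix: dropping sample(s) with zero total: ",
            paste(colnames(family_table)[drop], collapse = ", "))
    family_table <- family_table[, !drop, drop = FALSE]
  }
  pct <- relative_abundance(family_table)
  sel <- top_n_families(family_table, top_n)
  pct <- pct[sel$families, , drop = FALSE]
  pct[pct == 0] <- zero_sub
  out <- t(log10(pct))
  attr(out, "families") <- sel$families
  attr(out, "zero_sub") <- zero_sub
  out
}

#' Principal component analysis via singular value decomposition
#'
#' A first-party PCA: columns are centered (and scaled to unit standard
#' deviation by default) and the scores, loadings and variance fractions are
#' derived from the SVD of the transformed matrix. Zero-variance columns
#' cannot be scaled and are dropped with a warning. The sign of each component
#' is fixed so that the largest-magnitude loading is positive, making results
#' deterministic.
#'
#' @param x samples x variables numeric matrix.
#' @param center,scale Center/scale columns before decomposition.
#' @return Object of class `pca_ordination`: `scores` (samples x components),
#'   `loadings` (variables x components), `sdev`, `variance_fraction`.
#' @export
pca_ordination <- function(x, center = TRUE, scale = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) {
    stop("pca_ordination: at least two samples required", call. = FALSE)
  }
  if (scale) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      warning("pca_ordination: dropping zero-variance column(s): ",
              paste(colnames(x)[sds == 0], collapse = ", "))
      x <- x[, sds > 0, drop = FALSE]
    }
  }
  xs <- scale(x, center = center, scale = scale)
  sv <- svd(xs)
  k <- sum(sv$d > max(sv$d) * 1e-12)
  d <- sv$d[seq_len(k)]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(d, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-magnitude loading entry positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(x)
  rownames(loadings) <- colnames(x)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  sdev <- d / sqrt(nrow(x) - 1)
  structure(list(scores = scores, loadings = loadings, sdev = sdev,
                 variance_fraction = d^2 / sum(sv$d^2)),
            class = "pca_ordination")
}

#' @export
print.pca_ordination <- function(x, ...) {
  cat(sprintf("PCA: %d samples, %d components\n", nrow(x$scores),
              ncol(x$scores)))
  vf <- round(100 * x$variance_fraction[seq_len(min(4, length(x$variance_fraction)))], 1)
  cat("  variance explained (%):", paste(vf, collapse = ", "),
      if (length(x$variance_fraction) > 4) "..." else "", "\n")
  invisible(x)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(i, j) = sum|x_ik - x_jk| / sum(x_ik + x_jk)` over variables, for
#' non-negative community vectors; 0 for identical samples, 1 for samples with
#' disjoint support. Two all-zero samples are assigned distance 0 with a
#' warning.
#'
#' @param x samples x variables matrix of non-negative values.
#' @return A symmetric `dist`-convertible matrix with zero diagonal.
#' @export
#' @examples
#' bray_curtis(rbind(a = c(1, 1), b = c(0, 2)))  # d = 0.5
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("bray_curtis: values must be >= 0", call. = FALSE)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  warned <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- sum(x[i, ] + x[j, ])
      if (denom == 0) {
        if (!warned) {
          warning("bray_curtis: pair(s) of all-zero samples; distance set to 0")
          warned <- TRUE
        }
        d[i, j] <- d[j, i] <- 0
      } else {
        d[i, j] <- d[j, i] <- sum(abs(x[i, ] - x[j, ])) / denom
      }
    }
  }
  d
}

# Pseudo-F and R2 for a one-way design from a squared-distance matrix.
permanova_stat <- function(D2, groups) {
  n <- length(groups)
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      sub <- D2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ss_between <- ss_total - ss_within
  g <- length(unique(groups))
  f <- (ss_between / (g - 1)) / (ss_within / (n - g))
  list(F = f, R2 = ss_between / ss_total)
}

#' Permutational multivariate analysis of variance (one-way)
#'
#' First-party PERMANOVA on Bray-Curtis distances of square-root transformed
#' composition: total and within-group sums of squared distances give a
#' pseudo-F, whose null distribution is obtained by permuting group labels.
#' The p-value is `(1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @param x samples x variables matrix of non-negative proportions (or other
#'   non-negative community data), square-root transformed internally when
#'   `sqrt_transform = TRUE`.
#' @param groups Group label per sample (>= 2 groups, each >= 2 samples).
#' @param n_perm Number of label permutations.
#' @param seed Integer seed for the permutations.
#' @param sqrt_transform Apply the square-root transform before the distance
#'   computation.
#' @param distance Optional precomputed distance matrix; when supplied, `x`
#'   and `sqrt_transform` are ignored.
#' @return Object of class `permanova_result`: `F`, `R2`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
permanova <- function(x, groups, n_perm = 999, seed = 1L,
                      sqrt_transform = TRUE, distance = NULL) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) stop("permanova: at least two groups required",
                            call. = FALSE)
  if (any(tab < 2)) stop("permanova: every group needs >= 2 samples",
                         call. = FALSE)
  if (is.null(distance)) {
    x <- as.matrix(x)
    if (sqrt_transform) x <- sqrt(x)
    distance <- bray_curtis(x)
  } else {
    distance <- as.matrix(distance)
  }
  if (length(groups) != nrow(distance)) {
    stop("permanova: groups length must match the number of samples",
         call. = FALSE)
  }
  D2 <- distance^2
  obs <- permanova_stat(D2, groups)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    fp <- permanova_stat(D2, sample(groups))$F
    if (fp >= obs$F) exceed <- exceed + 1L
  }
  structure(list(F = obs$F, R2 = obs$R2,
                 p_value = (1 + exceed) / (1 + n_perm),
                 n_permutations = n_perm, seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations, seed %d)\n",
              x$F, x$R2, x$p_value, x$n_permutations, x$seed))
  invisible(x)
}

#' Principal coordinates embedding of a distance matrix
#'
#' Gower-centered double centering followed by an eigendecomposition. Axes
#' with negative eigenvalues (Bray-Curtis is semimetric) are retained
#' separately so that squared deviations can subtract their contribution, as
#' in the standard multivariate-dispersion procedure.
#'
#' @param distance Symmetric distance matrix.
#' @return List: `pos` (samples x axes, positive eigenvalues, scaled by
#'   sqrt(lambda)), `neg` (same for |negative| eigenvalues), `eig`.
#' @keywords internal
pcoa_embed <- function(distance) {
  d <- as.matrix(distance)
  n <- nrow(d)
  A <- -0.5 * d^2
  B <- A - rowMeans(A)[row(A)] - colMeans(A)[col(A)] + mean(A)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-10
  pos <- e$values > tol
  neg <- e$values < -tol
  list(
    pos = e$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(e$values[pos]), sum(pos)),
    neg = e$vectors[, neg, drop = FALSE] %*%
      diag(sqrt(-e$values[neg]), sum(neg)),
    eig = e$values
  )
}

# Deviations of every sample from its group centroid in PCoA space, with the
# negative-axis (imaginary-part) correction, and the one-way F on them.
dispersion_stat <- function(emb, groups) {
  dev2 <- numeric(length(groups))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    cp <- colMeans(emb$pos[idx, , drop = FALSE])
    dp <- sweep(emb$pos[idx, , drop = FALSE], 2, cp)
    dev2[idx] <- rowSums(dp^2)
    if (ncol(emb$neg) > 0) {
      cn <- colMeans(emb$neg[idx, , drop = FALSE])
      dn <- sweep(emb$neg[idx, , drop = FALSE], 2, cn)
      dev2[idx] <- dev2[idx] - rowSums(dn^2)
    }
  }
  z <- sqrt(pmax(dev2, 0))
  gm <- tapply(z, groups, mean)
  ng <- tapply(z, groups, length)
  ss_b <- sum(ng * (gm - mean(z))^2)
  ss_w <- sum((z - gm[groups])^2)
  g <- length(gm)
  n <- length(z)
  f <- if (ss_w == 0) {
    if (ss_b == 0) 0 else Inf
  } else {
    (ss_b / (g - 1)) / (ss_w / (n - g))
  }
  list(F = f, z = z, group_means = gm)
}

#' Homogeneity of multivariate dispersion test
#'
#' Embeds the distance matrix in principal-coordinates space, measures each
#' sample's deviation from its group centroid (squared deviations on
#' negative-eigenvalue axes are subtracted — the imaginary-part correction),
#' and tests group differences in mean deviation with a one-way F statistic.
#' The null distribution is obtained by permuting the group labels and
#' recomputing centroids and deviations for every permutation, which keeps the
#' test close to its nominal level even at small group sizes.
#'
#' @param distance Symmetric distance matrix.
#' @param groups Group label per sample.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Object of class `dispersion_result`: `F`, `p_value`,
#'   `group_means` (mean deviation per group), `deviations`.
#' @export
dispersion_test <- function(distance, groups, n_perm = 999, seed = 1L) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("dispersion_test: >= 2 groups with >= 2 samples each required",
         call. = FALSE)
  }
  emb <- pcoa_embed(distance)
  obs <- dispersion_stat(emb, groups)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (dispersion_stat(emb, sample(groups))$F >= obs$F) {
      exceed <- exceed + 1L
    }
  }
  structure(list(F = obs$F, p_value = (1 + exceed) / (1 + n_perm),
                 group_means = obs$group_means, deviations = obs$z,
                 n_permutations = n_perm, seed = seed),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("Dispersion homogeneity: F = %.3f, p = %.4g (%d permutations)\n",
              x$F, x$p_value, x$n_permutations))
  gm <- x$group_means
  cat("  mean deviation:",
      paste(sprintf("%s = %.4f", names(gm), gm), collapse = ", "), "\n")
  invisible(x)
}
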