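#' Gene x sample expression container
#'
#' @param counts Numeric matrix, genes x samples, rownames = gene ids,
#'   colnames matching `samples$sample`.
#' @param samples data.frame with columns `sample`, `condition`,
#'   `replicate`.
#' @param genes Optional gene annotation data.frame carried along.
#' @return An `ExpressionTable` (list with `counts`, `samples`, `genes`).
#' @export
expression_table <- function(counts, samples, genes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (!all(c("sample", "condition") %in% names(samples)))
    stop("samples needs columns sample, condition")
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample
  if (!identical(colnames(counts), samples$sample))
    counts <- counts[, samples$sample, drop = FALSE]
  if (any(counts < 0) || anyNA(counts)) stop("counts must be >= 0")
  structure(list(counts = counts, samples = samples, genes = genes),
            class = "ExpressionTable")
}

#' @export
print.ExpressionTable <- function(x, ...) {
  cat("ExpressionTable:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples (", length(unique(x$samples$condition)), "conditions )\n")
  invisible(x)
}

#' Counts per million
#'
#' `cpm[g,s] = counts[g,s] / library_size[s] * 1e6`; column sums are 1e6
#' by construction (before any gene filtering).
#'
#' @param counts Count matrix (genes x samples) or an
#'   [expression_table()].
#' @return CPM matrix of the same shape.
#' @export
compute_cpm <- function(counts) {
  if (inherits(counts, "ExpressionTable")) counts <- counts$counts
  libs <- colSums(counts)
  if (any(libs == 0)) stop("zero library size in sample(s): ",
                           paste(colnames(counts)[libs == 0], collapse = ", "))
  sweep(counts, 2, libs, "/") * 1e6
}

# moderated two-sample test on log2-cpm: gene-wise pooled variances are
# shrunk toward a lowess mean-variance trend with a fixed prior df
moderated_test <- function(logA, logB, prior_df = 4) {
  nA <- ncol(logA); nB <- ncol(logB)
  mA <- rowMeans(logA); mB <- rowMeans(logB)
  df_g <- nA + nB - 2
  s2 <- (rowSums((logA - mA)^2) + rowSums((logB - mB)^2)) / df_g
  amean <- (mA * nA + mB * nB) / (nA + nB)
  if (length(s2) >= 30) {
    lo <- stats::lowess(amean, sqrt(s2), f = 0.5)
    trend <- pmax(stats::approx(lo$x, lo$y, xout = amean, rule = 2,
                                ties = mean)$y, 0)^2
  } else {
    trend <- rep(mean(s2), length(s2))
  }
  s2_mod <- (prior_df * trend + df_g * s2) / (prior_df + df_g)
  se <- sqrt(pmax(s2_mod, 1e-12) * (1 / nA + 1 / nB))
  tt <- (mB - mA) / se
  tt[mB == mA] <- 0
  p <- 2 * stats::pt(-abs(tt), df_g + prior_df)
  list(t = tt, p = p, df = df_g + prior_df)
}

#' Differential expression between two conditions
#'
#' A simplified moderated test standing in for a full count-model DE
#' package: log2-CPM (pseudocount 0.5) per-gene two-sample t statistics
#' with variances shrunk toward the mean-variance trend, Benjamini-
#' Hochberg FDR, and the study's decision rule: differentially expressed
#' iff FDR < `alpha` and |logFC| > `lfc_min`.  `use_fdr = FALSE` gates on
#' the raw p-value instead.
#'
#' @param table An [expression_table()].
#' @param contrast Character vector `c(reference, alternative)` of
#'   condition labels; logFC is alternative over reference.
#' @param alpha FDR (or p) threshold, default 0.05.
#' @param lfc_min Absolute log2-fold-change threshold, default 0.5.
#' @param use_fdr Gate on BH FDR (default) or on raw p.
#' @return data.frame `gene_id`, `logFC`, `p`, `fdr`, `de`.
#' @export
differential_expression <- function(table, contrast, alpha = 0.05,
                                    lfc_min = 0.5, use_fdr = TRUE) {
  stopifnot(inherits(table, "ExpressionTable"), length(contrast) == 2L)
  sA <- table$samples$sample[table$samples$condition == contrast[1L]]
  sB <- table$samples$sample[table$samples$condition == contrast[2L]]
  if (length(sA) == 0L || length(sB) == 0L)
    stop("contrast condition(s) not found: ",
         paste(setdiff(contrast, table$samples$condition), collapse = ", "))
  if (length(sA) < 2L || length(sB) < 2L)
    stop("need >= 2 replicates per condition for a dispersion estimate; ",
         "use compute_cpm() for descriptive comparison")
  cpm <- compute_cpm(table)
  lg <- log2(cpm + 0.5)
  res <- moderated_test(lg[, sA, drop = FALSE], lg[, sB, drop = FALSE])
  logfc <- log2((rowMeans(cpm[, sB, drop = FALSE]) + 0.5) /
                  (rowMeans(cpm[, sA, drop = FALSE]) + 0.5))
  fdr <- stats::p.adjust(res$p, "BH")
  gate <- if (use_fdr) fdr else res$p
  data.frame(gene_id = rownames(table$counts), logFC = logfc, p = res$p,
             fdr = fdr, de = gate < alpha & abs(logfc) > lfc_min,
             stringsAsFactors = FALSE)
}

#' Differential expression of every condition against the reference
#'
#' @inheritParams differential_expression
#' @param reference Reference condition, default `"0h"`.
#' @return data.frame stacking [differential_expression()] results with a
#'   `contrast` column (`"<reference>:<condition>"`).
#' @export
de_all_contrasts <- function(table, reference = "0h", alpha = 0.05,
                             lfc_min = 0.5, use_fdr = TRUE) {
  conds <- setdiff(unique(table$samples$condition), reference)
  do.call(rbind, lapply(conds, function(cond) {
    d <- differential_expression(table, c(reference, cond), alpha,
                                 lfc_min, use_fdr)
    cbind(contrast = paste(reference, cond, sep = ":"), d)
  }))
}

# canonical kinetic shapes over (0h, 1Gy-6h, 1Gy-24h, 6Gy-6h, 6Gy-24h)
# used only to give k-means clusters stable, interpretable labels:
# 1 = down early at the high dose, 2 = down late at both doses,
# 3 = up late at the high dose only, 4 = up late at both doses
canonical_kinetic_profiles <- function() {
  rbind(`1` = c(0, 0,  0, -1, -1),
        `2` = c(0, 0, -1,  0, -1),
        `3` = c(0, 0,  0,  0,  1),
        `4` = c(0, 0,  1,  0,  1))
}

row_zscore <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  sd[sd == 0] <- 1
  (m - mu) / sd
}

#' K-means clustering of expression kinetics
#'
#' Clusters the per-gene z-scored mean log2-CPM profile over the five
#' conditions into `k` groups (k-means, `n_init` restarts, fixed seed).
#' For `k = 4` the clusters are relabelled deterministically by nearest
#' canonical kinetic shape, so cluster identity is stable across seeds
#' and matches the study's naming.
#'
#' @param table An [expression_table()].
#' @param gene_ids Genes to cluster, typically those differentially
#'   expressed in at least one contrast.
#' @param k Number of clusters, default 4.
#' @param seed Integer seed.
#' @param n_init Number of k-means restarts, default 50.
#' @return List with `labels` (named integer vector), `centers`
#'   (k x conditions, z-score units), `withinss`, `totss`.
#' @export
cluster_kinetics <- function(table, gene_ids, k = 4L, seed = 1L,
                             n_init = 50L) {
  stopifnot(inherits(table, "ExpressionTable"))
  if (length(gene_ids) < k)
    stop("fewer genes (", length(gene_ids), ") than clusters (", k, ")")
  cpm <- compute_cpm(table)
  conds <- unique(table$samples$condition)
  std <- c("0h", "1Gy-6h", "1Gy-24h", "6Gy-6h", "6Gy-24h")
  if (setequal(conds, std)) conds <- std     # canonical condition order
  prof <- sapply(conds, function(cond) {
    s <- table$samples$sample[table$samples$condition == cond]
    rowMeans(log2(cpm[gene_ids, s, drop = FALSE] + 0.5))
  })
  z <- row_zscore(prof)
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = n_init, iter.max = 100)
  labels <- km$cluster
  centers <- km$centers
  if (k == 4L && ncol(z) == 5L) {
    canon <- row_zscore(canonical_kinetic_profiles())
    perms <- perms4()
    cost <- apply(perms, 1, function(p)
      sum((centers[p, , drop = FALSE] - canon)^2))
    best <- perms[which.min(cost), ]      # best[j] = km cluster for label j
    relab <- integer(4); relab[best] <- 1:4
    labels <- relab[labels]
    centers <- centers[best, , drop = FALSE]
    rownames(centers) <- as.character(1:4)
  }
  list(labels = stats::setNames(labels, gene_ids), centers = centers,
       withinss = km$tot.withinss, totss = km$totss)
}

perms4 <- function() {
  p <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  as.matrix(p[apply(p, 1, function(r) length(unique(r)) == 4L), ])
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Vectors of equal length; label alphabets may differ.
#' @return The adjusted Rand index (1 = identical partitions, ~0 =
#'   independent).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
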