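#' Electrode adjacency for the sparse 10-20 montage
#'
#' Builds a neighbor relation from schematic 2-D positions of the 11-channel
#' grid (F3/Fz/F4, C3/Cz/C4, P3/Pz/P4, O1/O2): channels closer than
#' \code{max_dist} are neighbors. With the default threshold each channel is
#' linked to its lateral and anterior-posterior neighbors (plus the
#' occipital-parietal diagonals), and the minimum-neighbor requirement for
#' cluster membership is zero, so an isolated supra-threshold channel still
#' forms a singleton cluster.
#'
#' @param channels channel labels (subset of the 11-channel montage).
#' @param max_dist neighbor distance threshold in schematic head units.
#' @return symmetric, irreflexive logical adjacency matrix.
#' @export
montage_adjacency <- function(channels = c("F3", "Fz", "F4", "C3", "Cz", "C4",
                                           "P3", "Pz", "P4", "O1", "O2"),
                              max_dist = 0.45) {
  pos <- rbind(F3 = c(-0.4, 0.4), Fz = c(0, 0.4), F4 = c(0.4, 0.4),
               C3 = c(-0.4, 0), Cz = c(0, 0), C4 = c(0.4, 0),
               P3 = c(-0.4, -0.4), Pz = c(0, -0.4), P4 = c(0.4, -0.4),
               O1 = c(-0.2, -0.8), O2 = c(0.2, -0.8))
  unknown <- setdiff(channels, rownames(pos))
  if (length(unknown))
    stop("no schematic position for channel(s): ",
         paste(unknown, collapse = ", "))
  p <- pos[channels, , drop = FALSE]
  d <- as.matrix(stats::dist(p))
  adj <- d > 0 & d <= max_dist
  dimnames(adj) <- list(channels, channels)
  adj
}

#' Expand channel adjacency over a second (time or frequency) dimension
#'
#' Elements (channel, bin) are adjacent when they share the bin and the
#' channels are montage neighbors, or share the channel and the bins are
#' consecutive. Element order is channel-fastest within bin.
#'
#' @param adjacency channel adjacency matrix.
#' @param nbins number of time/frequency bins.
#' @return logical adjacency matrix over \code{nchan * nbins} elements.
#' @export
expand_adjacency <- function(adjacency, nbins) {
  nch <- nrow(adjacency)
  n <- nch * nbins
  out <- matrix(FALSE, n, n)
  for (b in seq_len(nbins)) {
    i <- (b - 1) * nch + seq_len(nch)
    out[i, i] <- adjacency
    if (b < nbins) {
      j <- b * nch + seq_len(nch)
      out[cbind(i, j)] <- TRUE
      out[cbind(j, i)] <- TRUE
    }
  }
  out
}

# Signed clusters of supra-threshold elements, via igraph components.
# Returns list of list(members, polarity, size).
find_clusters <- function(stat, supra, adjacency) {
  clusters <- list()
  for (pol in c(1, -1)) {
    sel <- which(supra & sign(stat) == pol)
    if (!length(sel)) next
    if (length(sel) == 1) {
      clusters[[length(clusters) + 1]] <-
        list(members = sel, polarity = pol, size = 1L)
      next
    }
    sub <- adjacency[sel, sel, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    comp <- igraph::components(g)
    for (k in seq_len(comp$no)) {
      members <- sel[comp$membership == k]
      clusters[[length(clusters) + 1]] <-
        list(members = members, polarity = pol, size = length(members))
    }
  }
  clusters
}

max_cluster_size <- function(stat, supra, adjacency) {
  cl <- find_clusters(stat, supra, adjacency)
  if (!length(cl)) 0L else max(vapply(cl, `[[`, integer(1), "size"))
}

# Element-wise two-sample t statistics: pooled-variance (independent) or
# paired. a, b: subjects x elements matrices.
elementwise_t <- function(a, b, paired) {
  if (paired) {
    d <- a - b
    n <- nrow(d)
    list(t = colMeans(d) / (apply(d, 2, stats::sd) / sqrt(n)), df = n - 1)
  } else {
    na <- nrow(a); nb <- nrow(b)
    va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
    sp <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    list(t = (colMeans(a) - colMeans(b)) / sqrt(sp * (1 / na + 1 / nb)),
         df = na + nb - 2)
  }
}

new_cluster_result <- function(clusters, null_max, n_perm, cluster_alpha,
                               alpha, labels, kind) {
  structure(list(clusters = clusters, null_max = null_max, n_perm = n_perm,
                 cluster_alpha = cluster_alpha, alpha = alpha,
                 labels = labels, kind = kind),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s, %d permutation(s)\n", x$kind, x$n_perm))
  if (!length(x$clusters)) {
    cat("  no supra-threshold clusters\n")
    return(invisible(x))
  }
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  cluster %d (%s): size %d, p = %.4g%s, effect = %.3g\n",
                i, if (cl$polarity > 0) "+" else "-", cl$size, cl$p,
                if (cl$p <= x$alpha) " *" else "", cl$effect))
    cat("    members:", paste(x$labels[cl$members], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Significant clusters of a cluster result
#' @param x a \code{cluster_result}.
#' @param alpha significance level (defaults to the stored critical alpha).
#' @return the significant clusters (list), possibly empty.
#' @export
significant_clusters <- function(x, alpha = x$alpha) {
  Filter(function(cl) cl$p <= alpha, x$clusters)
}

#' Cluster-based permutation test over channels (or channel-by-bin grids)
#'
#' Element-wise t statistics (pooled-variance independent or paired) are
#' thresholded two-sided at \code{cluster_alpha}; supra-threshold elements
#' are joined into signed clusters by the adjacency relation, each scored
#' by its size (max-size criterion). The null distribution of the maximum
#' cluster size over both signs is built by random group-label permutations
#' (independent) or condition sign flips (paired); Monte-Carlo p values use
#' the (b + 1)/(n + 1) correction. Cluster effect size is the mean Cohen's
#' d over the cluster members.
#'
#' @param group_a,group_b numeric matrices, subjects x elements; columns
#'   must align with \code{adjacency}.
#' @param adjacency logical adjacency matrix over elements, e.g.
#'   [montage_adjacency()] or [expand_adjacency()].
#' @param paired treat rows of the two groups as paired observations.
#' @param cluster_alpha element-inclusion alpha (two-sided, default 0.05).
#' @param n_perm number of random permutations (default 1000).
#' @param alpha critical (cluster-level) alpha, two-sided, default 0.05.
#' @param seed integer seed; results are deterministic given the seed.
#' @return a \code{cluster_result}; each cluster has members, polarity,
#'   size, Monte-Carlo p and mean Cohen's d.
#' @export
cluster_permutation_test <- function(group_a, group_b, adjacency,
                                     paired = FALSE, cluster_alpha = 0.05,
                                     n_perm = 1000, alpha = 0.05, seed = 1L) {
  a <- as.matrix(group_a); b <- as.matrix(group_b)
  if (ncol(a) != ncol(b)) stop("groups must have the same number of elements")
  if (ncol(a) != nrow(adjacency))
    stop("adjacency must match the number of elements")
  if (paired && nrow(a) != nrow(b)) stop("paired groups must have equal n")
  if (nrow(a) < 2 || nrow(b) < 2) stop("need at least 2 subjects per group")
  labels <- colnames(adjacency)
  if (is.null(labels)) labels <- as.character(seq_len(ncol(a)))

  obs <- elementwise_t(a, b, paired)
  tcrit <- stats::qt(1 - cluster_alpha / 2, obs$df)
  tobs <- obs$t
  tobs[is.na(tobs)] <- 0                 # zero-variance elements: no signal
  clusters <- find_clusters(tobs, abs(tobs) > tcrit, adjacency)

  # Canonicalize row order for the permutation loop so results are exactly
  # invariant to how subjects happen to be ordered in the input.
  if (paired) {
    ord <- do.call(order, as.data.frame(a - b))
    a <- a[ord, , drop = FALSE]; b <- b[ord, , drop = FALSE]
  } else {
    a <- a[do.call(order, as.data.frame(a)), , drop = FALSE]
    b <- b[do.call(order, as.data.frame(b)), , drop = FALSE]
  }
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      if (paired) {
        flip <- stats::runif(nrow(a)) < 0.5
        pa <- a; pb <- b
        pa[flip, ] <- b[flip, , drop = FALSE]
        pb[flip, ] <- a[flip, , drop = FALSE]
      } else {
        z <- rbind(a, b)
        idx <- sample.int(nrow(z))
        pa <- z[idx[seq_len(nrow(a))], , drop = FALSE]
        pb <- z[idx[-seq_len(nrow(a))], , drop = FALSE]
      }
      pt <- elementwise_t(pa, pb, paired)$t
      pt[is.na(pt)] <- 0
      max_cluster_size(pt, abs(pt) > tcrit, adjacency)
    }, numeric(1))
  })
  for (i in seq_along(clusters)) {
    clusters[[i]]$p <- (sum(null_max >= clusters[[i]]$size) + 1) / (n_perm + 1)
    clusters[[i]]$effect <-
      cohens_d_cluster(a, b, clusters[[i]]$members, paired = paired)
  }
  new_cluster_result(clusters, null_max, n_perm, cluster_alpha, alpha,
                     labels, if (paired) "paired t contrast"
                             else "independent t contrast")
}

# Spearman rho of y against each column of x (Pearson on ranks).
spearman_by_column <- function(x, y) {
  rx <- apply(x, 2, rank)
  stats::cor(rx, rank(y))[, 1]
}

rho_to_t <- function(rho, n, cap = 1e6) {
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  inf <- !is.finite(t)
  if (any(inf)) t[inf] <- sign(rho[inf]) * cap
  t
}

#' Cluster-corrected Spearman correlation over the montage
#'
#' Correlates a per-subject scalar (e.g. overnight change in task
#' proficiency) with a per-subject, per-channel measure (e.g. coupling
#' strength). Channel-wise Spearman rhos are transformed to t values via
#' t = rho * sqrt((n - 2) / (1 - rho^2)), thresholded two-sided at
#' \code{cluster_alpha}, clustered in space, and assessed against a null
#' distribution built by permuting the behavioral scalar across subjects
#' (max-size criterion). |rho| = 1 gives an infinite t and is treated as
#' supra-threshold with a capped t value. The reported cluster effect is
#' the mean rho over its members.
#'
#' @param x numeric matrix, subjects x channels.
#' @param y numeric vector, one scalar per subject.
#' @param adjacency channel adjacency matrix.
#' @inheritParams cluster_permutation_test
#' @return a \code{cluster_result} with per-channel rhos in
#'   \code{attr(, "rho")}.
#' @export
cluster_corrected_spearman <- function(x, y, adjacency, cluster_alpha = 0.05,
                                       n_perm = 1000, alpha = 0.05,
                                       seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 5) stop("need at least 5 subjects")
  if (length(y) != n) stop("y must have one value per subject (row of x)")
  if (ncol(x) != nrow(adjacency))
    stop("adjacency must match the number of channels")
  labels <- colnames(adjacency)
  if (is.null(labels)) labels <- as.character(seq_len(ncol(x)))

  rho <- spearman_by_column(x, y)
  tcrit <- stats::qt(1 - cluster_alpha / 2, n - 2)
  tobs <- rho_to_t(rho, n)
  clusters <- find_clusters(tobs, abs(tobs) > tcrit, adjacency)

  # Canonical subject order (by y, then x) for an input-order-invariant null.
  ord <- do.call(order, c(list(y), as.data.frame(x)))
  rx <- apply(x[ord, , drop = FALSE], 2, rank)
  ry <- rank(y[ord])
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      pr <- stats::cor(rx, ry[sample.int(n)])[, 1]
      pt <- rho_to_t(pr, n)
      max_cluster_size(pt, abs(pt) > tcrit, adjacency)
    }, numeric(1))
  })
  for (i in seq_along(clusters)) {
    clusters[[i]]$p <- (sum(null_max >= clusters[[i]]$size) + 1) / (n_perm + 1)
    clusters[[i]]$effect <- mean(rho[clusters[[i]]$members])
  }
  out <- new_cluster_result(clusters, null_max, n_perm, cluster_alpha, alpha,
                            labels, "Spearman correlation")
  attr(out, "rho") <- stats::setNames(rho, labels)
  out
}

#' Partial Spearman correlation
#'
#' Rank-transforms all variables, removes the covariates from the ranks of
#' x and y by linear regression, and correlates the residuals. With no
#' covariates this reduces exactly to the ordinary Spearman correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric vector/matrix of covariates.
#' @return partial rank correlation coefficient.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  if (is.null(covariates))
    return(stats::cor(x, y, method = "spearman"))
  z <- as.matrix(covariates)
  if (nrow(z) != length(x)) stop("covariates must match the sample size")
  if (length(x) <= ncol(z) + 2)
    stop("need n > number of covariates + 2")
  rz <- apply(z, 2, rank)
  if (qr(cbind(1, rz))$rank < ncol(rz) + 1) stop("collinear covariates")
  rx <- stats::lm.fit(cbind(1, rz), rank(x))$residuals
  ry <- stats::lm.fit(cbind(1, rz), rank(y))$residuals
  # a variable fully explained by the covariates has no residual rank
  # variance left: the partial correlation is 0 by construction
  eps <- 1e-8 * length(x)^2
  if (stats::var(rx) < eps || stats::var(ry) < eps) return(0)
  stats::cor(rx, ry)
}

#' Mean Cohen's d over a cluster
#'
#' Pooled-SD Cohen's d (or paired d: mean difference over SD of
#' differences) for every cluster member, averaged arithmetically.
#' Members with zero pooled SD are skipped with a warning.
#'
#' @param values_a,values_b subjects x elements matrices.
#' @param members element indices of the cluster (nonempty).
#' @param paired paired design flag.
#' @return mean Cohen's d.
#' @export
cohens_d_cluster <- function(values_a, values_b, members, paired = FALSE) {
  if (!length(members)) stop("cluster must be nonempty")
  a <- as.matrix(values_a); b <- as.matrix(values_b)
  d <- vapply(members, function(j) {
    if (paired) {
      dd <- a[, j] - b[, j]
      s <- stats::sd(dd)
      if (s == 0) return(NA_real_)
      mean(dd) / s
    } else {
      na <- nrow(a); nb <- nrow(b)
      sp <- sqrt(((na - 1) * stats::var(a[, j]) +
                    (nb - 1) * stats::var(b[, j])) / (na + nb - 2))
      if (sp == 0) return(NA_real_)
      (mean(a[, j]) - mean(b[, j])) / sp
    }
  }, numeric(1))
  if (anyNA(d)) warning(sum(is.na(d)), " member(s) with zero SD skipped")
  mean(d, na.rm = TRUE)
}
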