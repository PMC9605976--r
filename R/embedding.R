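## Developmental-trajectory embedding: standardization, PCA with a
## cumulative-variance retention rule, UMAP (n_neighbors = 15,
## min_dist = 0.2), geodesic trajectory ordering, and permutation-based
## divergence detection between genotypes at a critical germline size.

#' Standardize a morphometric cohort
#'
#' Column-wise z-scoring of the 24 quantitative parameters.  A wild-type
#' cohort is standardized on its own (\code{wt_alone}); genetically
#' manipulated cohorts are standardized pooled with their control
#' (\code{pooled_with_control}) so both genotypes share one set of
#' moments - pass the pooled table in that case.
#'
#' @param cohort data.frame of measured records (see [measure_cohort()]),
#'   or any table containing the columns of [morphometric_parameters()].
#' @param mode pooling mode; informational, both act on the table given.
#' @param columns parameter columns to standardize.
#' @return matrix of z-scores (rows = chambers) with attributes
#'   \code{center}, \code{scale}, \code{dropped} (zero-variance columns).
#' @export
standardize <- function(cohort,
                        mode = c("wt_alone", "pooled_with_control"),
                        columns = morphometric_parameters()) {
  mode <- match.arg(mode)
  if (nrow(cohort) < 2L) stopf("need at least 2 rows to standardize")
  columns <- intersect(columns, names(cohort))
  x <- as.matrix(cohort[, columns, drop = FALSE])
  storage.mode(x) <- "double"
  sds <- apply(x, 2L, sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop)) {
    warning(sprintf("dropping zero-variance column(s): %s",
                    paste(columns[drop], collapse = ", ")), call. = FALSE)
    x <- x[, !drop, drop = FALSE]
  }
  z <- scale(x)
  structure(z[, , drop = FALSE], center = attr(z, "scaled:center"),
            scale = attr(z, "scaled:scale"), dropped = columns[drop],
            mode = mode)
}

#' PCA with a cumulative-variance retention rule
#'
#' Principal components of a standardized cohort; the smallest number of
#' components whose cumulative explained variance exceeds the threshold
#' is retained (the published analysis retains the first five, with
#' cumulative variance above 90 percent).
#'
#' @param z standardized matrix from [standardize()].
#' @param cumvar_threshold retention threshold in (0, 1).
#' @return object of class \code{embedding_result} (partial): list with
#'   \code{pc_scores} (retained components), \code{cumvar}, \code{k},
#'   \code{rotation}, \code{sdev}.
#' @export
pca_select <- function(z, cumvar_threshold = 0.90) {
  if (cumvar_threshold <= 0 || cumvar_threshold >= 1)
    stopf("cumvar_threshold must lie in (0, 1)")
  p <- prcomp(z, center = FALSE, scale. = FALSE)
  cumvar <- cumsum(p$sdev^2) / sum(p$sdev^2)
  k <- which(cumvar > cumvar_threshold)[1L]
  structure(list(pc_scores = p$x[, seq_len(k), drop = FALSE],
                 cumvar = cumvar, k = k,
                 rotation = p$rotation, sdev = p$sdev),
            class = "embedding_result")
}

#' UMAP embedding with trajectory ordering
#'
#' Two-dimensional UMAP of the retained principal components
#' (n_neighbors = 15, min_dist = 0.2 by default), followed by a
#' developmental ordering of chambers: geodesic distance along the
#' k-nearest-neighbour graph of the embedding, from the chamber with the
#' smallest germline area.
#'
#' @param pc_scores matrix of PC scores (or an \code{embedding_result}).
#' @param germline_area vector of germline areas (used to root the
#'   trajectory); optional, defaults to the first score column.
#' @param n_neighbors,min_dist UMAP parameters.
#' @param seed integer seed (UMAP is stochastic; fixed by default).
#' @return object of class \code{embedding_result}: adds \code{umap_xy},
#'   \code{trajectory_order} (permutation of row indices),
#'   \code{geodesic}, \code{params}.
#' @export
umap_embed <- function(pc_scores, germline_area = NULL,
                       n_neighbors = 15L, min_dist = 0.2, seed = 0L) {
  res <- if (inherits(pc_scores, "embedding_result")) pc_scores
         else structure(list(pc_scores = as.matrix(pc_scores)),
                        class = "embedding_result")
  x <- res$pc_scores
  if (nrow(x) < n_neighbors + 1L)
    stopf("need at least n_neighbors + 1 = %d rows, got %d",
          n_neighbors + 1L, nrow(x))
  xy <- with_seed(seed,
    uwot::umap(x, n_neighbors = n_neighbors, min_dist = min_dist,
               n_threads = 1L, n_sgd_threads = 1L, batch = TRUE))
  colnames(xy) <- c("UMAP_1", "UMAP_2")
  root <- if (is.null(germline_area)) which.min(x[, 1L])
          else which.min(germline_area)
  geo <- knn_geodesic(xy, k = n_neighbors, root = root)
  res$umap_xy <- xy
  res$trajectory_order <- order(geo)
  res$geodesic <- geo
  res$params <- list(n_neighbors = n_neighbors, min_dist = min_dist,
                     seed = seed)
  res
}

## geodesic distances from `root` along the symmetric kNN graph of `xy`;
## unreachable nodes fall back to euclidean distance from the farthest
## reached point
knn_geodesic <- function(xy, k, root) {
  n <- nrow(xy)
  d <- as.matrix(dist(xy))
  nb <- t(apply(d, 1L, function(r) order(r)[2:(k + 1L)]))
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nb)))
  w <- d[edges]
  gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
  gr <- igraph::set_edge_attr(gr, "weight", value = w)
  geo <- igraph::distances(gr, v = root)[1L, ]
  if (any(!is.finite(geo))) {
    far <- max(geo[is.finite(geo)])
    geo[!is.finite(geo)] <- far + d[root, !is.finite(geo)]
  }
  geo
}

#' @export
print.embedding_result <- function(x, ...) {
  cat("Embedding result\n")
  if (!is.null(x$k))
    cat(sprintf("  %d PCs retained (cumulative variance %.1f%%)\n",
                x$k, 100 * x$cumvar[x$k]))
  if (!is.null(x$umap_xy))
    cat(sprintf("  UMAP %d x 2 (n_neighbors = %d, min_dist = %.2f, seed = %d)\n",
                nrow(x$umap_xy), x$params$n_neighbors, x$params$min_dist,
                x$params$seed))
  invisible(x)
}

#' @export
plot.embedding_result <- function(x, color = NULL, ...) {
  if (is.null(x$umap_xy)) stopf("no UMAP coordinates to plot")
  col <- if (is.null(color)) "grey30" else
    grDevices::hcl.colors(64, "Viridis")[cut(rank(color), 64L, labels = FALSE)]
  plot(x$umap_xy, col = col, pch = 16, cex = 0.7,
       xlab = "UMAP_1", ylab = "UMAP_2", ...)
  invisible(x)
}

#' Detect genotype divergence along the trajectory
#'
#' Projects control and mutant cohorts into a pooled embedding and scans
#' germline area upward for the first window in which the mutant
#' chambers' mean distance to their control neighbours exceeds a
#' permutation null band.  Family-wise control: the observed per-window
#' statistic is compared against the permutation distribution of the
#' maximum statistic over all windows.
#'
#' @param control,mutant measured cohort tables (same 24-parameter
#'   schema; must contain \code{germline_area}).
#' @param critical_size optional critical germline size (um^2); when
#'   given, the result reports whether the detected divergence area falls
#'   within \code{critical_ci}.
#' @param critical_ci numeric length-2 interval around the critical size.
#' @param window chambers per area window.
#' @param B number of label permutations.
#' @param alpha family-wise significance level.
#' @param n_neighbors neighbours for the distance statistic.
#' @param seed integer seed.
#' @return list with \code{diverged}, \code{area_at_divergence},
#'   \code{within_ci}, \code{stat} (per-window table), \code{threshold}.
#' @export
divergence_point <- function(control, mutant, critical_size = NULL,
                             critical_ci = NULL, window = 40L, B = 200L,
                             alpha = 0.05, n_neighbors = 10L, seed = 0L) {
  if (max(control$germline_area) < min(mutant$germline_area) ||
      max(mutant$germline_area) < min(control$germline_area))
    stopf("control and mutant area ranges do not overlap")
  pooled <- rbind(control[, morphometric_parameters()],
                  mutant[, morphometric_parameters()])
  lab <- rep(c(FALSE, TRUE), c(nrow(control), nrow(mutant)))  # TRUE = mutant
  area <- c(control$germline_area, mutant$germline_area)
  z <- standardize(pooled, "pooled_with_control")
  pc <- pca_select(z)$pc_scores
  ## area-ordered sliding windows (half-overlapping)
  o <- order(area)
  starts <- seq(1L, max(1L, length(o) - window + 1L), by = max(1L, window %/% 2L))
  wins <- lapply(starts, function(s) o[s:min(length(o), s + window - 1L)])
  d <- as.matrix(dist(pc))
  stat_for <- function(labels) {
    vapply(wins, function(ix) {
      mut <- ix[labels[ix]]; ctl <- ix[!labels[ix]]
      if (length(mut) < 3L || length(ctl) < 3L) return(NA_real_)
      k <- min(n_neighbors, length(ctl))
      mean(vapply(mut, function(i)
        mean(sort(d[i, ctl])[seq_len(k)]), numeric(1)))
    }, numeric(1))
  }
  obs <- stat_for(lab)
  null_max <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      perm <- sample(lab)
      max(stat_for(perm), na.rm = TRUE)
    }, numeric(1))
  })
  threshold <- quantile(null_max, 1 - alpha, names = FALSE, type = 7)
  sig <- !is.na(obs) & obs > threshold
  win_area <- vapply(wins, function(ix) median(area[ix]), numeric(1))
  diverged <- any(sig)
  ## onset: the lower edge of the first window exceeding the null band
  area_div <- if (diverged) min(area[wins[[which(sig)[1L]]]]) else NA_real_
  within_ci <- if (diverged && !is.null(critical_ci))
    area_div >= critical_ci[1L] && area_div <= critical_ci[2L] else NA
  list(diverged = diverged, area_at_divergence = area_div,
       within_ci = within_ci,
       stat = data.frame(area = win_area, stat = obs, significant = sig),
       threshold = threshold, critical_size = critical_size, alpha = alpha)
}
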