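# Conformational clustering: average-linkage agglomeration on a pairwise
# RMSD matrix, with cluster populations and representative ("middle")
# structures.

#' Pairwise RMSD matrix over (pooled, strided) frames
#'
#' All frames are first superposed once onto the reference structure (frame 1
#' of the first trajectory) using the alignment selection; the matrix entries
#' are then plain coordinate RMSDs over the measurement selection with no
#' per-pair refitting (`refit = TRUE` switches to per-pair refitting).
#'
#' @param trajs an `md_trajectory` or list of replicates (pooled).
#' @param align_query selection used for the one-shot alignment (default all
#'   CA atoms).
#' @param rmsd_query selection over which RMSD is measured (default CA).
#' @param stride keep every `stride`-th frame (default 1).
#' @param refit logical; per-pair Kabsch refit instead of the single shared
#'   alignment (default FALSE).
#' @return list: `matrix` (symmetric, zero diagonal), `frames` (data.frame
#'   `replicate`, `frame` mapping matrix rows to source frames).
#' @export
pairwise_rmsd_matrix <- function(trajs, align_query = "name CA",
                                 rmsd_query = "name CA", stride = 1L,
                                 refit = FALSE) {
  if (inherits(trajs, "md_trajectory")) trajs <- list(trajs)
  stopifnot(stride >= 1L)
  aidx <- select_atoms(trajs[[1]], align_query)$indices
  midx <- select_atoms(trajs[[1]], rmsd_query)$indices
  if (length(aidx) < 3L) stop("alignment selection has fewer than 3 atoms")
  ref <- frame_coords(trajs[[1]], 1L)
  coords <- list(); map <- list()
  for (r in seq_along(trajs)) {
    fr <- seq(1L, n_frames(trajs[[r]]), by = stride)
    for (f in fr) {
      fc <- frame_coords(trajs[[r]], f)
      al <- superpose(fc, ref, aidx)$coords
      coords[[length(coords) + 1L]] <- al[midx, , drop = FALSE]
      map[[length(map) + 1L]] <- data.frame(replicate = r, frame = f)
    }
  }
  n <- length(coords)
  if (n < 2L) stop("need at least 2 strided frames")
  m <- matrix(0, n, n)
  if (refit) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      m[i, j] <- m[j, i] <- superpose(coords[[i]], coords[[j]],
                                      seq_along(midx))$rmsd
    }
  } else {
    flat <- t(vapply(coords, as.vector, numeric(3L * length(midx))))
    m <- as.matrix(stats::dist(flat)) / sqrt(length(midx))
    dimnames(m) <- NULL
  }
  list(matrix = m, frames = do.call(rbind, map))
}

#' Average-linkage agglomerative clustering of frames
#'
#' Bottom-up agglomeration merging, at each step, the pair of clusters with
#' the smallest mean inter-cluster distance; the dendrogram is cut at
#' `n_clusters`.
#'
#' @param matrix symmetric distance matrix (or the list returned by
#'   [pairwise_rmsd_matrix()]).
#' @param n_clusters number of clusters to cut at (default 5).
#' @return list of class `"cluster_result"`: `labels` (per-frame cluster id),
#'   `merge` (the hclust merge history), `heights`, `n_clusters`.
#' @export
average_linkage <- function(matrix, n_clusters = 5L) {
  if (is.list(matrix) && !is.null(matrix$matrix)) matrix <- matrix$matrix
  n <- nrow(matrix)
  if (!is.numeric(n_clusters) || n_clusters < 1L || n_clusters > n) {
    stop("n_clusters must be in [1, n_frames]")
  }
  if (n_clusters == n) {
    return(structure(list(labels = seq_len(n), merge = NULL,
                          heights = numeric(), n_clusters = n),
                     class = "cluster_result"))
  }
  hc <- stats::hclust(stats::as.dist(matrix), method = "average")
  structure(list(labels = unname(stats::cutree(hc, k = n_clusters)),
                 merge = hc$merge, heights = hc$height,
                 n_clusters = as.integer(n_clusters)),
            class = "cluster_result")
}

#' Cluster populations and representative frames
#'
#' Population = cluster size / total frames; the representative ("middle")
#' structure of a cluster is the member with the smallest mean RMSD to all
#' other members (a singleton represents itself).  Clusters are reported in
#' descending population.
#'
#' @param result a `cluster_result`.
#' @param matrix the distance matrix the clustering was computed on.
#' @return data.frame with `cluster`, `size`, `population`,
#'   `representative` (frame index into the matrix).
#' @export
cluster_summary <- function(result, matrix) {
  if (is.list(matrix) && !is.null(matrix$matrix)) matrix <- matrix$matrix
  labs <- result$labels
  out <- do.call(rbind, lapply(sort(unique(labs)), function(cl) {
    mem <- which(labs == cl)
    rep <- if (length(mem) == 1L) mem else {
      sub <- matrix[mem, mem, drop = FALSE]
      mem[which.min(rowSums(sub) / (length(mem) - 1L))]
    }
    data.frame(cluster = cl, size = length(mem),
               population = length(mem) / length(labs),
               representative = rep)
  }))
  out[order(-out$population, out$cluster), , drop = FALSE]
}
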