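#' Stack subject centrality maps into a matrix
#'
#' @param maps List of `centrality_map` objects sharing one mask.
#' @return Subjects x voxels numeric matrix (in-mask voxels, mask order).
#' @export
stack_maps <- function(maps) {
  mask <- maps[[1]]$mask
  for (m in maps) {
    if (!all(dim(m$mask) == dim(mask)) || sum(m$mask != mask) > 0) {
      stopf("all maps must share the same mask")
    }
  }
  do.call(rbind, purrr::map(maps, function(m) m$values[mask]))
}

# design matrices for the group partial-F test; design: tibble with `group`
# and covariate columns
ancova_design_matrices <- function(design, covariates = NULL) {
  d <- tibble::as_tibble(design)
  if (!"group" %in% names(d)) stopf("`design` must contain a `group` column")
  covariates <- covariates %||% setdiff(names(d), c("group", "subject", "participant_id"))
  d$group <- factor(d$group)
  x_full <- stats::model.matrix(stats::reformulate(c("group", covariates)), data = d)
  x_red <- stats::model.matrix(stats::reformulate(c(covariates, "1")), data = d)
  for (x in list(x_full, x_red)) {
    if (qr(x)$rank < ncol(x)) {
      stopf("rank-deficient design (columns: %s)", paste(colnames(x), collapse = ", "))
    }
  }
  list(full = x_full, reduced = x_red, n_groups = nlevels(d$group))
}

# vectorized per-voxel partial F for the group factor given the two designs
partial_f_map <- function(y, x_full, x_red) {
  qf <- qr(x_full)
  qr_ <- qr(x_red)
  rss <- function(qrx, y) {
    qty <- qr.qty(qrx, y)[seq_len(qrx$rank), , drop = FALSE]
    colSums(y^2) - colSums(qty^2)
  }
  rss1 <- rss(qf, y)
  rss0 <- rss(qr_, y)
  q <- ncol(x_full) - ncol(x_red)
  df2 <- nrow(y) - ncol(x_full)
  f <- ((rss0 - rss1) / q) / (rss1 / df2)
  list(f = pmax(f, 0), df1 = q, df2 = df2)
}

#' Voxel-wise ANCOVA for group differences
#'
#' Per-voxel partial F test for the group factor: the full model regresses
#' each voxel's value on group plus covariates, the reduced model on the
#' covariates only, and F = ((RSS0 - RSS1)/q) / (RSS1/(N - p)). Intended for
#' smoothed, standardized centrality maps with covariates age, sex,
#' education and mean FD.
#'
#' @param maps List of `centrality_map`s or a subjects x voxels matrix.
#' @param design Data frame with `group` and covariate columns, rows in map
#'   order.
#' @param mask Logical 3D mask (required when `maps` is a matrix; taken from
#'   the maps otherwise).
#' @return A `stat_map`: per-voxel F values on the mask, with `df1`, `df2`
#'   and uncorrected p values. [tidy()] returns the voxel table.
#' @export
voxelwise_ancova <- function(maps, design, mask = NULL) {
  if (is.list(maps) && inherits(maps[[1]], "centrality_map")) {
    mask <- maps[[1]]$mask
    y <- stack_maps(maps)               # subjects x voxels
  } else {
    if (is.null(mask)) stopf("`mask` required when `maps` is a matrix")
    y <- as.matrix(maps)
  }
  if (nrow(y) != nrow(design)) stopf("design rows must match the number of maps")
  dm <- ancova_design_matrices(design)
  pf <- partial_f_map(y, dm$full, dm$reduced)
  structure(
    list(f = pf$f, df1 = pf$df1, df2 = pf$df2,
         p = stats::pf(pf$f, pf$df1, pf$df2, lower.tail = FALSE),
         mask = mask, design = tibble::as_tibble(design), y = y),
    class = "stat_map"
  )
}

#' @export
print.stat_map <- function(x, ...) {
  cat("<stat_map> partial F, df (", x$df1, ", ", x$df2, "), ",
      length(x$f), " voxels; max F = ", signif(max(x$f), 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.stat_map <- function(x, ...) {
  co <- which(x$mask, arr.ind = TRUE)
  tibble::tibble(x = co[, 1], y = co[, 2], z = co[, 3],
                 statistic = x$f, p.value = x$p)
}

#' @export
glance.stat_map <- function(x, ...) {
  tibble::tibble(df1 = x$df1, df2 = x$df2, max_f = max(x$f),
                 n_voxels = length(x$f),
                 prop_p05 = mean(x$p < 0.05))
}

# neighbour offsets for 6/18/26-connectivity
connectivity_offsets <- function(connectivity = 26) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(off != 0)
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1,
                 stopf("connectivity must be 6, 18 or 26"))
  off[keep, , drop = FALSE]
}

# label connected components among `voxels` (linear indices into a grid of
# dims `d`) under the given lattice connectivity; returns an integer label
# per voxel
label_components <- function(voxels, d, connectivity = 26) {
  if (length(voxels) == 0) return(integer(0))
  off <- connectivity_offsets(connectivity)
  co <- arrayInd(voxels, d)
  key <- (co[, 3] - 1) * d[1] * d[2] + (co[, 2] - 1) * d[1] + co[, 1]
  lookup <- new.env(hash = TRUE, size = length(voxels))
  for (i in seq_along(key)) assign(as.character(key[i]), i, envir = lookup)
  labels <- integer(length(voxels))
  cur <- 0L
  for (i in seq_along(voxels)) {
    if (labels[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    labels[i] <- cur
    while (length(queue) > 0) {
      j <- queue[[1]]
      queue <- queue[-1]
      nb <- sweep(off, 2, co[j, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      nbkey <- (nb[, 3] - 1) * d[1] * d[2] + (nb[, 2] - 1) * d[1] + nb[, 1]
      for (k in nbkey) {
        hit <- lookup[[as.character(k)]]
        if (!is.null(hit) && labels[hit] == 0L) {
          labels[hit] <- cur
          queue <- c(queue, hit)
        }
      }
    }
  }
  labels
}

# max suprathreshold cluster extent for an F map (vector on mask)
max_cluster_extent <- function(f, mask, f_crit, connectivity) {
  supra <- which(mask)[f > f_crit]
  if (length(supra) == 0) return(0L)
  lab <- label_components(supra, dim(mask), connectivity)
  max(tabulate(lab))
}

#' Permutation cluster-level correction
#'
#' Familywise-error control over suprathreshold clusters of a voxel-wise
#' ANCOVA map. Voxels with uncorrected p below `voxel_p` are grouped into
#' connected components (26-neighbourhood by default); each observed
#' cluster's extent is compared against the permutation distribution of the
#' maximal cluster extent under the Freedman-Lane scheme (residuals of the
#' reduced, covariates-only model are permuted, the reduced fit is added
#' back, and the full-model partial F map is recomputed).
#'
#' @param statmap A `stat_map` from [voxelwise_ancova()] (carries the data
#'   and design needed for permutation).
#' @param voxel_p Voxel-level threshold (default 0.005).
#' @param cluster_p Cluster-level corrected threshold (default 0.05).
#' @param n_perm Number of permutations (default 1000; below 100 a warning
#'   is issued).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param seed Integer seed for the permutation stream.
#' @return A `cluster_result`: tibble of clusters (`cluster`, `extent`,
#'   `peak_f`, peak coordinates, `p_corrected`, `significant`), the cluster
#'   label array, and the permutation null extents. [tidy()] returns the
#'   cluster table.
#' @export
cluster_correct <- function(statmap, voxel_p = 0.005, cluster_p = 0.05,
                            n_perm = 1000, connectivity = 26, seed = 1L) {
  stopifnot(inherits(statmap, "stat_map"))
  if (n_perm < 100) warnf("n_perm = %d is low; corrected p values will be coarse", n_perm)
  f_crit <- stats::qf(voxel_p, statmap$df1, statmap$df2, lower.tail = FALSE)
  d <- dim(statmap$mask)
  supra <- which(statmap$mask)[statmap$f > f_crit]
  labels <- label_components(supra, d, connectivity)

  dm <- ancova_design_matrices(statmap$design)
  qred <- qr(dm$reduced)
  fitted_red <- qr.fitted(qred, statmap$y)
  resid_red <- qr.resid(qred, statmap$y)
  n <- nrow(statmap$y)

  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- sample.int(n)
      ystar <- fitted_red + resid_red[perm, , drop = FALSE]
      fstar <- partial_f_map(ystar, dm$full, dm$reduced)$f
      as.integer(max_cluster_extent(fstar, statmap$mask, f_crit, connectivity))
    }, integer(1))
  })

  if (length(supra) == 0) {
    clusters <- tibble::tibble(cluster = integer(0), extent = integer(0),
                               peak_f = numeric(0), peak_x = integer(0),
                               peak_y = integer(0), peak_z = integer(0),
                               p_corrected = numeric(0), significant = logical(0))
  } else {
    fmask <- statmap$f
    voxf <- fmask[statmap$f > f_crit]
    clusters <- purrr::map(sort(unique(labels)), function(lb) {
      vox <- supra[labels == lb]
      extent <- length(vox)
      fs <- voxf[labels == lb]
      peak <- arrayInd(vox[which.max(fs)], d)
      pcorr <- (1 + sum(null_max >= extent)) / (n_perm + 1)
      tibble::tibble(cluster = lb, extent = extent, peak_f = max(fs),
                     peak_x = peak[1], peak_y = peak[2], peak_z = peak[3],
                     p_corrected = pcorr, significant = pcorr < cluster_p)
    }) %>% purrr::list_rbind() %>% dplyr::arrange(dplyr::desc(.data$extent))
  }
  label_array <- array(0L, d)
  label_array[supra] <- labels
  structure(
    list(clusters = clusters, labels = label_array, mask = statmap$mask,
         f_crit = f_crit, null_max_extent = null_max,
         params = list(voxel_p = voxel_p, cluster_p = cluster_p,
                       n_perm = n_perm, connectivity = connectivity, seed = seed)),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", nrow(x$clusters), " suprathreshold cluster(s), ",
      sum(x$clusters$significant), " significant at cluster p < ",
      x$params$cluster_p, " (", x$params$n_perm, " permutations)\n", sep = "")
  if (nrow(x$clusters) > 0) print(x$clusters)
  invisible(x)
}

#' @export
tidy.cluster_result <- function(x, ...) x$clusters

#' Extract per-subject ROI means over a cluster
#'
#' @param maps List of `centrality_map`s or a subjects x voxels matrix (mask
#'   order).
#' @param cluster_result A `cluster_result`, or an integer/logical vector of
#'   in-mask voxel indices.
#' @param cluster Which cluster label to use when a `cluster_result` is
#'   given (default: the largest significant cluster, falling back to the
#'   largest).
#' @return Numeric vector: each subject's mean map value over the cluster
#'   voxels.
#' @export
extract_roi_means <- function(maps, cluster_result, cluster = NULL) {
  y <- if (is.list(maps) && inherits(maps[[1]], "centrality_map")) {
    stack_maps(maps)
  } else {
    as.matrix(maps)
  }
  if (inherits(cluster_result, "cluster_result")) {
    cl <- cluster_result$clusters
    if (nrow(cl) == 0) stopf("no suprathreshold clusters to extract")
    lb <- cluster %||% (if (any(cl$significant)) cl$cluster[cl$significant][1] else cl$cluster[1])
    vox_lin <- which(cluster_result$labels == lb)
    idx <- match(vox_lin, which(cluster_result$mask))
  } else if (is.logical(cluster_result)) {
    idx <- which(cluster_result)
  } else {
    idx <- as.integer(cluster_result)
  }
  if (length(idx) == 0 || any(is.na(idx))) stopf("empty or invalid cluster voxel set")
  rowMeans(y[, idx, drop = FALSE])
}
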