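#' Construct a two-channel 3D image stack
#'
#' Arrays are indexed `[y, x, z]`; both channels and the binary nucleus mask
#' must share dimensions. Voxel size is metadata only - all distances are
#' reported in voxel units and treated as isotropic.
#'
#' @param fish FISH-channel array.
#' @param sc35 SC35-channel array.
#' @param mask logical/0-1 nucleus mask array.
#' @param voxel_size named numeric `c(x=,y=,z=)` in micrometres (metadata).
#' @return list of class `image_stack`.
#' @export
image_stack <- function(fish, sc35, mask, voxel_size = c(x = 1, y = 1, z = 1)) {
  stopifnot(identical(dim(fish), dim(sc35)), identical(dim(fish), dim(mask)),
            length(dim(fish)) == 3L)
  if (any(fish < 0) || any(sc35 < 0)) stop("intensities must be non-negative")
  structure(list(fish = fish, sc35 = sc35, mask = mask != 0,
                 voxel_size = voxel_size), class = "image_stack")
}

#' Otsu threshold of an intensity sample
#'
#' Histogram-based two-class threshold (256 levels over the sample range).
#' Invariant under rescaling by a positive constant.
#'
#' @param values numeric vector of intensities.
#' @return scalar threshold; voxels strictly above it are foreground.
#' @export
otsu_threshold <- function(values) {
  r <- range(values)
  if (r[1] == r[2]) return(r[2])  # flat image: nothing above threshold
  EBImage::otsu(matrix(values, ncol = 1L), range = r, levels = 256L)
}

#' Binary foreground mask of one channel within the nucleus
#'
#' The automatic threshold is Otsu's, floored at the in-nucleus mean plus
#' three standard deviations so that a channel carrying no real signal (pure
#' background) yields an essentially empty mask instead of a split of the
#' noise distribution. Both parts scale linearly, so the mask is invariant
#' under positive intensity rescaling.
#'
#' @param stack an [image_stack()].
#' @param channel `"fish"` or `"sc35"`.
#' @param threshold fixed threshold overriding the automatic one (optional).
#' @return logical array: inside nucleus and above threshold.
#' @export
threshold_mask <- function(stack, channel = c("sc35", "fish"), threshold = NULL) {
  channel <- match.arg(channel)
  img <- stack[[channel]]
  if (!any(stack$mask)) stop("empty nucleus mask")
  if (is.null(threshold)) threshold <- .auto_threshold(img[stack$mask])
  img > threshold & stack$mask
}

# Otsu floored at mean + 3 SD of the in-nucleus intensities
.auto_threshold <- function(v) {
  max(otsu_threshold(v), mean(v) + 3 * stats::sd(v))
}

# connected components of a 3D logical array by vectorised min-label
# propagation over the voxel neighbourhood ("3d" = 26-neighbourhood, "slice" =
# 8-neighbourhood per z-slice). Converges in O(component diameter) sweeps.
.label_components <- function(mask, connectivity = c("3d", "slice")) {
  connectivity <- match.arg(connectivity)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(list())
  d <- dim(mask)
  ai <- arrayInd(idx, d)
  pos <- integer(prod(d))
  pos[idx] <- seq_len(n)
  offs <- expand.grid(dy = -1:1, dx = -1:1, dz = if (connectivity == "3d") -1:1 else 0)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0 & offs$dz == 0), ]
  nb <- matrix(0L, n, nrow(offs))
  for (k in seq_len(nrow(offs))) {
    ny <- ai[, 1] + offs$dy[k]; nx <- ai[, 2] + offs$dx[k]; nz <- ai[, 3] + offs$dz[k]
    ok <- ny >= 1L & ny <= d[1] & nx >= 1L & nx <= d[2] & nz >= 1L & nz <= d[3]
    nkey <- (nz - 1L) * (d[1] * d[2]) + (nx - 1L) * d[1] + ny
    nb[ok, k] <- pos[nkey[ok]]
  }
  lab <- seq_len(n)
  repeat {
    nl <- lab
    for (k in seq_len(ncol(nb))) {
      v <- nb[, k]
      has <- v > 0L
      nl[has] <- pmin(nl[has], nl[v[has]])
    }
    if (identical(nl, lab)) break
    lab <- nl
  }
  comps <- unname(split(idx, lab))
  comps[order(vapply(comps, min, numeric(1)))]
}

.particle_set <- function(stack, channel, threshold, min_voxels, connectivity,
                          cls) {
  fg <- threshold_mask(stack, channel, threshold)
  comps <- .label_components(fg, connectivity)
  comps <- comps[vapply(comps, length, 1L) >= min_voxels]
  d <- dim(stack$mask)
  img <- stack[[channel]]
  if (length(comps)) {
    lens <- lengths(comps)
    vi <- unlist(comps, use.names = FALSE)
    grp <- rep.int(seq_along(comps), lens)
    ai <- arrayInd(vi, d)
    w <- img[vi]
    sw <- as.vector(rowsum(w, grp))
    tab <- data.table(
      id = seq_along(comps), n_voxels = as.integer(lens),
      cy = as.vector(rowsum(ai[, 1] * w, grp)) / sw,
      cx = as.vector(rowsum(ai[, 2] * w, grp)) / sw,
      cz = as.vector(rowsum(ai[, 3] * w, grp)) / sw,
      total_intensity = sw)
  } else {
    tab <- data.table(id = integer(), n_voxels = integer(), cy = numeric(),
                      cx = numeric(), cz = numeric(), total_intensity = numeric())
  }
  structure(list(table = tab, voxels = comps, dim = d), class = cls)
}

#' Detect FISH spots by 3D particle analysis
#'
#' Thresholds the channel within the nucleus (Otsu by default), labels
#' connected components (26-neighbourhood in 3D by default; a per-slice mode
#' is available), discards components below `min_voxels`, and reports
#' intensity-weighted centroids. Deterministic.
#'
#' @param stack an [image_stack()].
#' @param channel channel to analyse.
#' @param min_voxels minimum component size.
#' @param connectivity `"3d"` (26-neighbourhood) or `"slice"`.
#' @param threshold fixed threshold overriding Otsu.
#' @return object of class `spot_set`: `table` (id, n_voxels, cy, cx, cz,
#'   total_intensity), `voxels` (list of linear indices), `dim`.
#' @export
detect_spots <- function(stack, channel = "fish", min_voxels = 4L,
                         connectivity = c("3d", "slice"), threshold = NULL) {
  .particle_set(stack, channel, threshold, min_voxels,
                match.arg(connectivity), "spot_set")
}

#' Segment SC35 clusters
#'
#' Same machinery as [detect_spots()] with its own defaults; two blobs closer
#' than the optical resolution merge into one reported cluster.
#'
#' @inheritParams detect_spots
#' @return object of class `cluster_set` (same structure as `spot_set`).
#' @export
segment_clusters <- function(stack, channel = "sc35", min_voxels = 5L,
                             connectivity = c("3d", "slice"), threshold = NULL) {
  .particle_set(stack, channel, threshold, min_voxels,
                match.arg(connectivity), "cluster_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat("spot_set:", nrow(x$table), "spot(s)\n"); invisible(x)
}
#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", nrow(x$table), "cluster(s)\n"); invisible(x)
}

#' Conservative per-spot colocalization call
#'
#' A FISH spot is ISOLATED only when none of its voxels carries SC35 signal;
#' a single SC35-positive voxel makes it colocalized. This is deliberately
#' conservative for calling isolation.
#'
#' @param spots a `spot_set`.
#' @param sc35_mask logical array (same grid) of SC35-positive voxels, e.g.
#'   from [threshold_mask()].
#' @return logical vector, one flag per spot.
#' @export
call_colocalization <- function(spots, sc35_mask) {
  stopifnot(identical(dim(sc35_mask), spots$dim))
  vapply(spots$voxels, function(vi) any(sc35_mask[vi]), logical(1))
}

#' Per-image colocalized fraction
#'
#' @param coloc logical vector of per-spot colocalization flags for one image.
#' @return fraction colocalized; `NA` with a warning for an image with zero
#'   spots (such images are excluded from group comparisons).
#' @export
image_summary <- function(coloc) {
  if (length(coloc) == 0L) {
    warning("image with zero FISH spots excluded")
    return(NA_real_)
  }
  mean(coloc)
}

#' 3D distance from each FISH spot to its nearest SC35 cluster
#'
#' Euclidean center-to-center distance in voxel units (voxels treated as
#' isotropic).
#'
#' @param spots a `spot_set`.
#' @param clusters a `cluster_set` with at least one cluster.
#' @return numeric vector of distances, one per spot.
#' @export
nearest_cluster_distances <- function(spots, clusters) {
  if (nrow(clusters$table) == 0L) stop("no SC35 clusters")
  if (nrow(spots$table) == 0L) return(numeric(0))
  sc <- as.matrix(spots$table[, c("cy", "cx", "cz")])
  cc <- as.matrix(clusters$table[, c("cy", "cx", "cz")])
  vapply(seq_len(nrow(sc)), function(i) {
    sqrt(min(colSums((t(cc) - sc[i, ])^2)))
  }, numeric(1))
}

#' Histogram of spot-to-cluster distances at integer voxel distances
#'
#' Bin `d` (for d = 1..max_bin) holds the count of distances in `(d-1, d]`;
#' bin 1 additionally includes exact zeros, so every distance <= `max_bin`
#' lands in exactly one bin. Larger distances are excluded from the bins but
#' reported in `remainder`; bins + remainder conserve the input count.
#'
#' @param distances numeric vector of distances (voxels).
#' @param max_bin largest integer distance binned.
#' @return list with `counts` (named, bins 1..max_bin) and `remainder`.
#' @export
distance_histogram <- function(distances, max_bin = 10L) {
  b <- pmax(ceiling(distances), 1L)
  counts <- tabulate(b[b <= max_bin], nbins = max_bin)
  names(counts) <- as.character(seq_len(max_bin))
  list(counts = counts, remainder = sum(b > max_bin))
}

#' Compare two groups of imaging measurements
#'
#' Welch's t-test on per-image colocalized fractions, or a two-sample
#' Kolmogorov-Smirnov test on pooled spot-to-cluster distance samples.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @param test `"t"` (Welch) or `"ks"`.
#' @return list with `statistic`, `p.value`, `test`.
#' @export
compare_groups <- function(a, b, test = c("t", "ks")) {
  test <- match.arg(test)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  if (test == "t") {
    if (stats::var(a) == 0 && stats::var(b) == 0)
      stop("compare_groups: zero-variance groups; t-test undefined")
    res <- stats::t.test(a, b, var.equal = FALSE)
  } else {
    res <- suppressWarnings(stats::ks.test(a, b))
  }
  list(statistic = unname(res$statistic), p.value = res$p.value, test = test)
}

#' Write an image stack as multi-page TIFFs
#'
#' One 16-bit multi-page TIFF per channel plus the mask; intensities are
#' stored as `round(x)/65535` so the round trip is exact for integer-valued
#' intensities up to 65535.
#'
#' @param stack an [image_stack()].
#' @param prefix output path prefix; writes `<prefix>_fish.tif`,
#'   `<prefix>_sc35.tif`, `<prefix>_mask.tif`.
#' @return invisibly, the three paths.
#' @export
write_image_stack <- function(stack, prefix) {
  wr <- function(arr, path, scale) {
    pages <- lapply(seq_len(dim(arr)[3]), function(z)
      pmin(pmax(round(arr[, , z]) / scale, 0), 1))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  }
  paths <- paste0(prefix, c("_fish.tif", "_sc35.tif", "_mask.tif"))
  wr(stack$fish, paths[1], 65535)
  wr(stack$sc35, paths[2], 65535)
  wr(stack$mask * 1, paths[3], 1)
  invisible(paths)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param prefix path prefix used at write time.
#' @param voxel_size metadata voxel size.
#' @return an [image_stack()].
#' @export
read_image_stack <- function(prefix, voxel_size = c(x = 1, y = 1, z = 1)) {
  rd <- function(path, scale) {
    pages <- tiff::readTIFF(path, all = TRUE)
    arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
    for (z in seq_along(pages)) arr[, , z] <- round(pages[[z]] * scale)
    arr
  }
  image_stack(rd(paste0(prefix, "_fish.tif"), 65535),
              rd(paste0(prefix, "_sc35.tif"), 65535),
              rd(paste0(prefix, "_mask.tif"), 1) > 0.5,
              voxel_size = voxel_size)
}
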