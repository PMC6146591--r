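#' Simulate single-nucleus two-channel 3D image stacks
#'
#' Emulates the DNA FISH + SC35 immunofluorescence acquisition: per nucleus an
#' ellipsoidal mask, 20-35 Gaussian SC35 blobs, and 1-3 FISH spots. Each spot
#' is planted colocalized (centred within `coloc_offset` voxels of a cluster
#' centre) with probability `coloc_prob`, otherwise placed at least
#' `noncoloc_min_dist` voxels (centre-to-centre) from every cluster, so
#' recovered calls track planted truth. Gaussian noise rides on a flat
#' background; no point-spread or chromatic realism is attempted.
#'
#' @param n_cells number of nuclei to simulate.
#' @param coloc_prob planted per-spot colocalization probability.
#' @param config a [sim_config()] (its `imaging` element is used).
#' @param seed integer seed.
#' @return list with `cells` (list of [image_stack()]) and `truth`
#'   (data.table: cell, spot, coloc, n_clusters, n_spots).
#' @export
simulate_images <- function(n_cells, coloc_prob, config = sim_config(),
                            seed = 1L) {
  set.seed(seed)
  p <- config$imaging
  d <- unname(p$dim[c("y", "x", "z")])
  ctr <- (d + 1) / 2
  ax <- unname(p$semi_axes)
  ey <- ((seq_len(d[1]) - ctr[1]) / ax[1])^2
  ex <- ((seq_len(d[2]) - ctr[2]) / ax[2])^2
  ez <- ((seq_len(d[3]) - ctr[3]) / ax[3])^2
  mask <- outer(outer(ey, ex, "+"), ez, "+") <= 1

  in_nucleus <- function(pt, margin) {
    sum(((pt - ctr) / (ax - margin))^2) <= 1
  }
  rand_point <- function(margin) {
    for (batch in 1:20) {   # 50 candidates per batch; ~52% land in the ellipsoid
      cand <- matrix(stats::runif(150) * 2 - 1, 50, 3)
      v <- rowSums(cand^2)
      hit <- which(v <= 1)
      if (length(hit))
        return(ctr + cand[hit[1L], ] * (ax - margin))
    }
    stop("could not sample a point inside the nucleus")
  }
  # one Gaussian blob: linear voxel indices and intensities of its 3-sigma box
  blob_patch <- function(c0, amp, sigma) {
    r <- ceiling(3 * sigma)
    yr <- max(1, floor(c0[1] - r)):min(d[1], ceiling(c0[1] + r))
    xr <- max(1, floor(c0[2] - r)):min(d[2], ceiling(c0[2] + r))
    zr <- max(1, floor(c0[3] - r)):min(d[3], ceiling(c0[3] + r))
    g <- outer(outer(exp(-(yr - c0[1])^2 / (2 * sigma^2)),
                     exp(-(xr - c0[2])^2 / (2 * sigma^2))),
               exp(-(zr - c0[3])^2 / (2 * sigma^2)))
    list(idx = as.vector(outer(outer(yr, (xr - 1) * d[1], "+"),
                               (zr - 1) * d[1] * d[2], "+")),
         val = amp * as.vector(g))
  }
  mask_idx <- which(mask)

  cells <- vector("list", n_cells)
  truth <- list()
  for (ci in seq_len(n_cells)) {
    n_cl <- sample(p$n_clusters[1]:p$n_clusters[2], 1L)
    n_sp <- sample(p$n_spots[1]:p$n_spots[2], 1L)
    ccent <- matrix(NA_real_, n_cl, 3)
    for (k in seq_len(n_cl)) {
      placed <- FALSE
      for (att in 1:1000) {
        pt <- rand_point(p$nucleus_margin)
        if (k == 1L || min(sqrt(colSums((t(ccent[seq_len(k - 1L), , drop = FALSE]) - pt)^2))) >=
              p$min_cluster_sep) { ccent[k, ] <- pt; placed <- TRUE; break }
      }
      if (!placed) stop("could not place SC35 cluster ", k)
    }
    scent <- matrix(NA_real_, n_sp, 3)
    coloc <- stats::runif(n_sp) < coloc_prob
    for (k in seq_len(n_sp)) {
      placed <- FALSE
      for (att in 1:1000) {
        if (coloc[k]) {
          pt <- ccent[sample.int(n_cl, 1L), ] +
            (stats::runif(3) * 2 - 1) * p$coloc_offset
          if (!in_nucleus(pt, p$nucleus_margin)) next
        } else {
          pt <- rand_point(p$nucleus_margin)
          if (min(sqrt(colSums((t(ccent) - pt)^2))) < p$noncoloc_min_dist) next
        }
        if (k > 1L && min(sqrt(colSums((t(scent[seq_len(k - 1L), , drop = FALSE]) - pt)^2))) <
              p$min_spot_sep) next
        scent[k, ] <- pt; placed <- TRUE; break
      }
      if (!placed) stop("could not place FISH spot ", k, " in cell ", ci)
    }
    # noisy background only inside the nucleus; detection never looks outside
    sc35 <- numeric(prod(d)); dim(sc35) <- d
    fish <- numeric(prod(d)); dim(fish) <- d
    sc35[mask_idx] <- pmax(stats::rnorm(length(mask_idx), p$background, p$noise_sd), 0)
    fish[mask_idx] <- pmax(stats::rnorm(length(mask_idx), p$background, p$noise_sd), 0)
    for (k in seq_len(n_cl)) {
      bp <- blob_patch(ccent[k, ], p$cluster_amp, p$cluster_sigma)
      sc35[bp$idx] <- sc35[bp$idx] + bp$val
    }
    for (k in seq_len(n_sp)) {
      bp <- blob_patch(scent[k, ], p$spot_amp, p$spot_sigma)
      fish[bp$idx] <- fish[bp$idx] + bp$val
    }
    cells[[ci]] <- image_stack(fish, sc35, mask)
    truth[[ci]] <- data.table(cell = ci, spot = seq_len(n_sp), coloc = coloc,
                              n_clusters = n_cl, n_spots = n_sp)
  }
  list(cells = cells, truth = rbindlist(truth))
}

#' Run the colocalization analysis over a set of simulated or loaded cells
#'
#' Per cell: segment SC35 clusters, detect FISH spots, call the conservative
#' pixel-overlap colocalization, and record nearest-cluster centre distances.
#'
#' @param cells list of [image_stack()] objects.
#' @param image_of integer vector assigning each cell to an image (per-image
#'   fractions pool all spots of an image); defaults to one image per cell.
#' @return list with `spots` (per-spot table: image, cell, coloc, distance)
#'   and `images` (per-image colocalized fraction).
#' @export
analyze_cells <- function(cells, image_of = seq_along(cells)) {
  stopifnot(length(image_of) == length(cells))
  rows <- list()
  for (ci in seq_along(cells)) {
    st <- cells[[ci]]
    sp <- detect_spots(st)
    t_sc <- .auto_threshold(st$sc35[st$mask])   # one threshold per SC35 channel
    cl <- segment_clusters(st, threshold = t_sc)
    if (nrow(sp$table) == 0L) next
    cm <- threshold_mask(st, "sc35", threshold = t_sc)
    fl <- call_colocalization(sp, cm)
    dd <- if (nrow(cl$table)) nearest_cluster_distances(sp, cl)
          else rep(NA_real_, nrow(sp$table))
    rows[[length(rows) + 1L]] <- data.table(
      image = image_of[ci], cell = ci, spot = seq_along(fl),
      coloc = fl, distance = dd)
  }
  spots <- rbindlist(rows)
  images <- spots[, .(fraction = mean(coloc), n_spots = .N), by = image]
  setorder(images, image)
  list(spots = spots, images = images)
}
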