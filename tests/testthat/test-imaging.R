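test_that("spot detection recovers planted Gaussian spots deterministically", {
  st <- blob_stack(fish_centers = rbind(c(10, 10, 4), c(24, 22, 5)))
  sp <- detect_spots(st)
  expect_equal(nrow(sp$table), 2L)
  got <- sp$table[order(sp$table$cy), ]
  expect_lt(max(abs(got$cy - c(10, 24))), 1)
  expect_lt(max(abs(got$cx - c(10, 22))), 1)
  expect_lt(max(abs(got$cz - c(4, 5))), 1)
  # same stack twice: identical output
  sp2 <- detect_spots(st)
  expect_identical(sp$table, sp2$table)
  # blank channel: zero spots
  blank <- blob_stack()
  expect_equal(nrow(detect_spots(blank)$table), 0L)
  # empty nucleus mask errors
  st0 <- st; st0$mask[] <- FALSE
  expect_error(detect_spots(st0), "mask")
})

test_that("cluster segmentation counts separated blobs and merges near ones", {
  cents <- as.matrix(expand.grid(y = c(6, 16, 26), x = c(6, 16, 26), z = 4))
  st <- blob_stack(sc35_centers = cents)
  cl <- segment_clusters(st)
  expect_equal(nrow(cl$table), 9L)
  # two blobs closer than the resolution merge into one component
  near <- blob_stack(sc35_centers = rbind(c(10, 10, 4), c(12, 11, 4)))
  expect_equal(nrow(segment_clusters(near)$table), 1L)
})

test_that("detection is invariant under positive intensity rescaling", {
  st <- blob_stack(fish_centers = rbind(c(10, 10, 4), c(24, 22, 5)))
  st2 <- st; st2$fish <- st$fish * 7.3
  a <- detect_spots(st); b <- detect_spots(st2)
  expect_identical(a$voxels, b$voxels)
})

test_that("3D versus per-slice connectivity differ exactly on diagonal z-links", {
  m <- array(FALSE, dim = c(5, 5, 3))
  m[2, 2, 1] <- TRUE; m[3, 3, 2] <- TRUE  # 26-connected, not slice-connected
  st <- image_stack(fish = m * 100, sc35 = m * 0, mask = array(TRUE, dim(m)))
  c3 <- detect_spots(st, min_voxels = 1, connectivity = "3d", threshold = 50)
  cs <- detect_spots(st, min_voxels = 1, connectivity = "slice", threshold = 50)
  expect_equal(nrow(c3$table), 1L)
  expect_equal(nrow(cs$table), 2L)
})

test_that("the conservative colocalization rule flags any SC35-positive voxel", {
  st <- blob_stack(fish_centers = rbind(c(10, 10, 4), c(24, 24, 5)))
  sp <- detect_spots(st)
  mask <- array(FALSE, dim = dim(st$fish))
  expect_identical(call_colocalization(sp, mask), c(FALSE, FALSE))
  # a single positive voxel inside spot 1 flips it
  mask[sp$voxels[[1]][1]] <- TRUE
  expect_identical(call_colocalization(sp, mask), c(TRUE, FALSE))
  # upper bound relative to a zero-radius centroid rule
  ctr_rule <- vapply(seq_len(nrow(sp$table)), function(i)
    mask[round(sp$table$cy[i]), round(sp$table$cx[i]), round(sp$table$cz[i])],
    logical(1))
  expect_true(all(call_colocalization(sp, mask) >= ctr_rule))
})

test_that("per-image summaries average spots and exclude empty images", {
  expect_equal(image_summary(c(TRUE, TRUE, FALSE)), 2 / 3)
  expect_equal(image_summary(c(TRUE, TRUE)), 1)
  expect_warning(na <- image_summary(logical(0)), "zero")
  expect_true(is.na(na))
  # pooled fraction equals the spot-weighted mean of per-image fractions
  imgs <- list(c(TRUE, FALSE), c(TRUE, TRUE, TRUE), FALSE)
  pooled <- mean(unlist(imgs))
  fr <- vapply(imgs, image_summary, numeric(1))
  w <- lengths(imgs)
  expect_equal(sum(fr * w) / sum(w), pooled)
})

test_that("nearest-cluster distances are Euclidean and match brute force", {
  mk <- function(tab) structure(list(table = data.table::as.data.table(tab)),
                                class = "spot_set")
  sp <- mk(data.frame(id = 1:2, cy = c(0, 0), cx = c(0, 3), cz = c(0, 4)))
  cl <- mk(data.frame(id = 1:2, cy = c(0, 10), cx = c(0, 10), cz = c(0, 10)))
  expect_equal(nearest_cluster_distances(sp, cl), c(0, 5))
  expect_error(nearest_cluster_distances(sp, mk(data.frame(cy = 1, cx = 1, cz = 1)[0, ])),
               "no SC35")
  set.seed(15)
  for (rep in 1:10) {
    s <- mk(data.frame(cy = runif(6, 0, 30), cx = runif(6, 0, 30), cz = runif(6, 0, 8)))
    k <- mk(data.frame(cy = runif(9, 0, 30), cx = runif(9, 0, 30), cz = runif(9, 0, 8)))
    got <- nearest_cluster_distances(s, k)
    want <- vapply(seq_len(6), function(i) {
      min(sqrt((k$table$cy - s$table$cy[i])^2 + (k$table$cx - s$table$cx[i])^2 +
                 (k$table$cz - s$table$cz[i])^2))
    }, numeric(1))
    expect_equal(got, want)
  }
})

test_that("distance histograms bin (d-1, d], keep zeros in bin 1, conserve counts", {
  h <- distance_histogram(c(0.5, 1.0, 7.3))
  expect_equal(unname(h$counts[c(1, 8)]), c(2L, 1L))
  expect_equal(sum(h$counts) + h$remainder, 3L)
  h0 <- distance_histogram(numeric(0))
  expect_equal(sum(h0$counts), 0L)
  set.seed(16)
  d <- c(0, runif(50, 0, 15))
  h2 <- distance_histogram(d)
  expect_equal(sum(h2$counts) + h2$remainder, length(d))
  expect_gte(h2$counts[1], 1L)  # the exact zero lands in bin 1
})

test_that("group comparisons: Welch t and KS with degenerate-input policy", {
  set.seed(17)
  x <- runif(20); y <- runif(20)
  ks <- compare_groups(x, y, "ks")
  expect_equal(ks$statistic, oracle_ks_stat(x, y), tolerance = 1e-12)
  same <- compare_groups(x, x, "ks")
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(compare_groups(c(1, 1, 1), c(1, 1), "t"), "zero-variance")
  expect_silent(compare_groups(c(1, 1, 1), c(1, 1), "ks"))
  tt <- compare_groups(rnorm(10, 5), rnorm(10, 0), "t")
  expect_lt(tt$p.value, 0.01)
})

test_that("image stacks round-trip through 16-bit multi-page TIFFs", {
  st <- blob_stack(fish_centers = rbind(c(10, 10, 4)))
  st$fish <- round(st$fish); st$sc35 <- round(st$sc35)
  prefix <- file.path(withr::local_tempdir(), "cell1")
  write_image_stack(st, prefix)
  back <- read_image_stack(prefix)
  expect_equal(back$fish, st$fish)
  expect_equal(back$sc35, st$sc35)
  expect_equal(back$mask, st$mask)
})
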