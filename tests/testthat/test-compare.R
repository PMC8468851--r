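mask_from <- function(m, psz = 1) mx_mask(m > 0, psz)

test_that("labeling handles empty masks and analytic squares", {
  expect_length(label_aggregates(mask_from(matrix(0, 5, 5))), 0)

  m <- matrix(0, 12, 12)
  m[2:4, 2:4] <- 1
  m[8:10, 7:9] <- 1
  aggs <- label_aggregates(mask_from(m, psz = 2))
  expect_length(aggs, 2)
  expect_equal(aggs[[1]]$area_px, 9)
  expect_equal(aggs[[1]]$centroid_px, c(3, 3))
  expect_equal(aggs[[2]]$centroid_px, c(9, 8))
  expect_equal(aggs[[2]]$centroid_um, c(x = 16, y = 18))
  expect_equal(aggs[[2]]$area_um2, 36)
})

test_that("diagonal-touching pixels form one 8-connected component", {
  m <- matrix(0, 6, 6)
  m[2, 2] <- 1; m[3, 3] <- 1; m[4, 2] <- 1   # chain touching only diagonally
  aggs <- label_aggregates(mask_from(m))
  expect_length(aggs, 1)
  expect_equal(aggs[[1]]$area_px, 3)
  # flood-fill oracle on a random blob field: component count must match a
  # queue-based 8-neighbour flood fill
  set.seed(44)
  rnd <- matrix(runif(30 * 30) > 0.7, 30, 30)
  flood_count <- function(m) {
    seen <- matrix(FALSE, nrow(m), ncol(m)); n <- 0
    for (s in which(m & !seen)) {
      if (seen[s]) next
      n <- n + 1
      queue <- s
      seen[s] <- TRUE
      while (length(queue)) {
        q <- queue[1]; queue <- queue[-1]
        r <- (q - 1) %% nrow(m) + 1; c <- (q - 1) %/% nrow(m) + 1
        for (dr in -1:1) for (dc in -1:1) {
          rr <- r + dr; cc <- c + dc
          if (rr >= 1 && rr <= nrow(m) && cc >= 1 && cc <= ncol(m) &&
              m[rr, cc] && !seen[rr, cc]) {
            seen[rr, cc] <- TRUE
            queue <- c(queue, (cc - 1) * nrow(m) + rr)
          }
        }
      }
    }
    n
  }
  expect_length(label_aggregates(mask_from(rnd)), flood_count(rnd))
})

test_that("identical masks match perfectly", {
  sc <- generate_aggregate_scene(aggregate_scene_params(
    n_aggregates = 3, field_size_px = 96, seed = 5))
  aggs <- sc$truth$aggregates
  res <- match_aggregates(aggs, aggs)
  expect_equal(nrow(res$pairs), 3)
  expect_true(all(res$pairs$displacement_um == 0))
  expect_true(all(res$pairs$area_ratio == 1))
  expect_length(res$ref_unmatched, 0)
  expect_length(res$test_unmatched, 0)
})

test_that("a 2-px shifted blob matches with displacement 2 um", {
  m1 <- matrix(0, 20, 20); m1[5:10, 5:10] <- 1
  m2 <- matrix(0, 20, 20); m2[7:12, 5:10] <- 1   # shifted 2 rows, overlaps
  res <- match_aggregates(label_aggregates(mask_from(m1)),
                          label_aggregates(mask_from(m2)))
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$pairs$displacement_um, 2)
  expect_equal(res$pairs$area_ratio, 1)
})

test_that("pairs with area ratio above two are mismatches", {
  m1 <- matrix(0, 30, 30); m1[11:20, 11:20] <- 1          # area 100
  m2 <- matrix(0, 30, 30); m2[8:23, 8:23] <- 1            # area 256 > 2x
  res <- match_aggregates(label_aggregates(mask_from(m1)),
                          label_aggregates(mask_from(m2)))
  expect_equal(nrow(res$pairs), 0)
  expect_equal(res$ref_unmatched, 1L)
  expect_equal(res$test_unmatched, 1L)
})

test_that("non-overlapping nearest pairs are mismatches", {
  m1 <- matrix(0, 30, 30); m1[2:7, 2:7] <- 1
  m2 <- matrix(0, 30, 30); m2[20:25, 20:25] <- 1
  res <- match_aggregates(label_aggregates(mask_from(m1)),
                          label_aggregates(mask_from(m2)))
  expect_equal(nrow(res$pairs), 0)
})

test_that("one test blob over two ref blobs pairs with the nearer centroid", {
  m_ref <- matrix(0, 40, 40)
  m_ref[5:12, 10:17] <- 1                   # centroid row 8.5
  m_ref[26:33, 10:17] <- 1                  # centroid row 29.5
  m_test <- matrix(0, 40, 40)
  m_test[6:30, 12:15] <- 1                  # overlaps both, centroid row 18
  ref <- label_aggregates(mask_from(m_ref))
  test <- label_aggregates(mask_from(m_test))
  # make areas comparable so only distance decides
  res <- match_aggregates(ref, test)
  if (nrow(res$pairs) == 1) {
    expect_equal(res$pairs$ref_id, 1L)      # nearer of the two (9.5 vs 11.5 px)
    expect_equal(res$ref_unmatched, 2L)
  } else {
    # ratio rule may reject; then both refs are unmatched
    expect_equal(sort(res$ref_unmatched), c(1L, 2L))
  }
})

test_that("pixel confusion counts complement and quadrant fixtures", {
  sc <- generate_aggregate_scene(aggregate_scene_params(
    n_aggregates = 3, field_size_px = 64, seed = 9))
  m <- sc$truth$mask
  same <- pixel_confusion(m, m)
  expect_equal(same$FP, 0); expect_equal(same$FN, 0)
  expect_equal(same$TP, sum(m$values))

  comp <- pixel_confusion(m, mx_mask(!m$values, 1))
  expect_equal(comp$TP, 0); expect_equal(comp$TN, 0)

  left <- mask_from(cbind(matrix(1, 10, 5), matrix(0, 10, 5)))
  top <- mask_from(rbind(matrix(1, 5, 10), matrix(0, 5, 10)))
  q <- pixel_confusion(left, top)
  expect_equal(c(q$TP, q$FP, q$TN, q$FN), c(25, 25, 25, 25))
  expect_equal(q$TP + q$FP + q$TN + q$FN, 100)
})

test_that("precision/recall arithmetic, sentinels, and ref/test symmetry", {
  expect_equal(precision(list(TP = 50, FP = 50, FN = 0)), 0.5)
  expect_equal(recall(list(TP = 50, FP = 50, FN = 0)), 1.0)
  expect_equal(precision(list(TP = 0, FP = 3, FN = 2)), 0)
  expect_true(is.na(precision(list(TP = 0, FP = 0, FN = 5))))
  expect_true(is.na(recall(list(TP = 0, FP = 5, FN = 0))))

  a <- mask_from(matrix(sample(0:1, 100, TRUE), 10, 10))
  b <- mask_from(matrix(sample(0:1, 100, TRUE), 10, 10))
  ab <- pixel_confusion(a, b)
  ba <- pixel_confusion(b, a)
  expect_equal(ab$FP, ba$FN)
  expect_equal(ab$FN, ba$FP)
  expect_equal(precision(ab), recall(ba))
})

test_that("matched truth-vs-segmentation displacement stays below a pixel", {
  sc <- generate_aggregate_scene(aggregate_scene_params(
    n_aggregates = 4, background_noise_sigma = 0, field_size_px = 160,
    seed = 29))
  seg <- segment_aggregates(sc$fluor_like)
  res <- match_aggregates(sc$truth$aggregates, label_aggregates(seg))
  expect_equal(nrow(res$pairs), 4)
  expect_lt(mean(res$pairs$displacement_um), 1)  # 1 um/px here
})

test_that("confusion label image uses the four-color palette", {
  left <- mask_from(cbind(matrix(1, 4, 2), matrix(0, 4, 2)))
  top <- mask_from(rbind(matrix(1, 2, 4), matrix(0, 2, 4)))
  conf <- pixel_confusion(left, top)
  rgb <- confusion_rgb(conf)
  expect_equal(dim(rgb), c(4, 4, 3))
  expect_equal(rgb[1, 1, ], c(1, 1, 1))     # TP white
  expect_equal(rgb[4, 4, ], c(0, 0, 0))     # TN black
  expect_equal(rgb[4, 1, ], c(1, 0, 0))     # FN red
})
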