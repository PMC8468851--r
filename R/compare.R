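#' Extract aggregate records from a binary mask
#'
#' Enumerates 8-connected foreground components in raster order (row-major
#' order of each component's first pixel) and computes per-aggregate
#' centroids in pixels and micrometers, areas, and pixel sets.
#'
#' @param mask An [mx_mask()].
#' @return A list of class `mx_aggregates`; each element is a record with
#'   `id`, `centroid_px` (row, col), `centroid_um` (x, y), `area_px`,
#'   `area_um2`, `pixels` (n x 2 matrix of row/col) and `lin` (linear pixel
#'   indices). The pixel size is attached as an attribute. An empty mask
#'   gives an empty list.
#' @export
label_aggregates <- function(mask) {
  stopifnot(inherits(mask, "mx_mask"))
  m <- mask$values
  psz <- mask$pixel_size_um
  out <- list()
  if (any(m)) {
    lab <- label_components_8(m)
    nlab <- max(lab)
    nr <- nrow(m); nc <- ncol(m)
    lin <- which(lab > 0)
    labs <- lab[lin]
    rows <- ((lin - 1L) %% nr) + 1L
    cols <- ((lin - 1L) %/% nr) + 1L
    # raster (row-major) position of each component's first pixel
    rm_pos <- (rows - 1L) * nc + cols
    first <- tapply(rm_pos, labs, min)
    order_ids <- order(first)
    for (new_id in seq_len(nlab)) {
      old <- order_ids[new_id]
      sel <- labs == old
      r <- rows[sel]; cc <- cols[sel]
      cen <- c(mean(r), mean(cc))
      out[[new_id]] <- list(
        id = new_id,
        centroid_px = cen,
        centroid_um = c(x = cen[2] * psz, y = cen[1] * psz),
        area_px = sum(sel),
        area_um2 = sum(sel) * psz^2,
        pixels = cbind(row = r, col = cc),
        lin = lin[sel])
    }
  }
  structure(out, class = "mx_aggregates", pixel_size_um = psz,
            dim_px = dim(m))
}

#' @export
print.mx_aggregates <- function(x, ...) {
  cat(sprintf("<mx_aggregates> %d components\n", length(x)))
  if (length(x)) print(utils::head(aggregates_table(x), 10))
  invisible(x)
}

#' Tabulate aggregate records
#'
#' @param aggs An `mx_aggregates` list from [label_aggregates()].
#' @return A data frame with one row per aggregate.
#' @export
aggregates_table <- function(aggs) {
  if (!length(aggs)) {
    return(data.frame(id = integer(), row = numeric(), col = numeric(),
                      x_um = numeric(), y_um = numeric(),
                      area_px = integer(), area_um2 = numeric()))
  }
  do.call(rbind, lapply(aggs, function(a) data.frame(
    id = a$id, row = a$centroid_px[1], col = a$centroid_px[2],
    x_um = a$centroid_um[["x"]], y_um = a$centroid_um[["y"]],
    area_px = a$area_px, area_um2 = a$area_um2)))
}

# 8-connected labeling: 4-connected pass (EBImage::bwlabel) followed by
# union-find merging of labels that touch diagonally
label_components_8 <- function(m) {
  lab <- as.matrix(EBImage::bwlabel(m * 1))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]       # down-right diagonal neighbors
  cc <- lab[-nr, -1]; d <- lab[-1, -nc]      # down-left diagonal neighbors
  pairs <- rbind(cbind(a[a > 0 & b > 0], b[a > 0 & b > 0]),
                 cbind(cc[cc > 0 & d > 0], d[cc > 0 & d > 0]))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

#' Match aggregates between two segmentations
#'
#' Candidate pairs (one aggregate from each segmentation) are ranked by
#' ascending centroid distance, ties broken by lower reference id then lower
#' test id, and assigned greedily one-to-one. A pair is accepted only if the
#' two pixel sets overlap and neither aggregate is more than twice as large
#' as the other; a pair violating either rule is a mismatch and both
#' aggregates remain available (they end up unmatched unless a later
#' candidate accepts them).
#'
#' @param ref,test `mx_aggregates` lists from [label_aggregates()], computed
#'   on same-shape masks.
#' @return A list of class `mx_match` with `pairs` (data frame: `ref_id`,
#'   `test_id`, `displacement_um`, `area_ratio` = test/ref),
#'   `ref_unmatched`, `test_unmatched` (integer id vectors), and `summary`
#'   (mean/sd displacement and area ratio).
#' @export
match_aggregates <- function(ref, test) {
  stopifnot(inherits(ref, "mx_aggregates"), inherits(test, "mx_aggregates"))
  if (!is.null(attr(ref, "dim_px")) && !is.null(attr(test, "dim_px")) &&
      !identical(attr(ref, "dim_px"), attr(test, "dim_px")))
    stop("aggregate records come from masks of different shapes")
  psz <- attr(ref, "pixel_size_um")
  nr <- length(ref); nt <- length(test)
  pairs <- data.frame(ref_id = integer(), test_id = integer(),
                      displacement_um = numeric(), area_ratio = numeric())
  if (nr > 0 && nt > 0) {
    cand <- expand.grid(i = seq_len(nr), j = seq_len(nt))
    cand$d <- vapply(seq_len(nrow(cand)), function(k) {
      sqrt(sum((ref[[cand$i[k]]]$centroid_px -
                test[[cand$j[k]]]$centroid_px)^2))
    }, numeric(1))
    cand <- cand[order(cand$d, cand$i, cand$j), ]
    used_r <- logical(nr); used_t <- logical(nt)
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (used_r[i] || used_t[j]) next
      ai <- ref[[i]]$area_px; aj <- test[[j]]$area_px
      overlap <- length(intersect(ref[[i]]$lin, test[[j]]$lin)) > 0
      if (!overlap || max(ai, aj) / min(ai, aj) > 2) next
      used_r[i] <- TRUE; used_t[j] <- TRUE
      pairs <- rbind(pairs, data.frame(
        ref_id = i, test_id = j,
        displacement_um = cand$d[k] * psz,
        area_ratio = aj / ai))
    }
    ref_unmatched <- which(!used_r)
    test_unmatched <- which(!used_t)
  } else {
    ref_unmatched <- seq_len(nr)
    test_unmatched <- seq_len(nt)
  }
  structure(list(
    pairs = pairs,
    ref_unmatched = as.integer(ref_unmatched),
    test_unmatched = as.integer(test_unmatched),
    summary = list(
      n_matched = nrow(pairs),
      displacement_um_mean = if (nrow(pairs)) mean(pairs$displacement_um) else NA_real_,
      displacement_um_sd = if (nrow(pairs) > 1) stats::sd(pairs$displacement_um) else NA_real_,
      area_ratio_mean = if (nrow(pairs)) mean(pairs$area_ratio) else NA_real_,
      area_ratio_sd = if (nrow(pairs) > 1) stats::sd(pairs$area_ratio) else NA_real_)),
    class = "mx_match")
}

#' @export
print.mx_match <- function(x, ...) {
  cat(sprintf("<mx_match> %d pairs, %d ref / %d test unmatched\n",
              nrow(x$pairs), length(x$ref_unmatched), length(x$test_unmatched)))
  if (nrow(x$pairs))
    cat(sprintf("  displacement %.2f um (mean), area ratio %.3f (mean)\n",
                x$summary$displacement_um_mean, x$summary$area_ratio_mean))
  invisible(x)
}

#' Pixel-level confusion between two masks
#'
#' Treating `ref` as ground truth: TP = foreground in both, FP = foreground
#' only in `test`, TN = background in both, FN = foreground only in `ref`.
#' The label image uses the conventional palette: TP white, FP orange,
#' TN black, FN red.
#'
#' @param ref,test Same-shape [mx_mask()] objects.
#' @return A list of class `mx_confusion` with integer counts `TP`, `FP`,
#'   `TN`, `FN`, the `label_image` (integer matrix coded 1 = TP, 2 = FP,
#'   3 = TN, 4 = FN) and its `palette`.
#' @export
pixel_confusion <- function(ref, test) {
  stopifnot(inherits(ref, "mx_mask"), inherits(test, "mx_mask"))
  if (!identical(dim(ref$values), dim(test$values)))
    stop("masks have different shapes")
  r <- ref$values; s <- test$values
  lab <- matrix(3L, nrow(r), ncol(r))   # TN
  lab[r & s] <- 1L                      # TP
  lab[!r & s] <- 2L                     # FP
  lab[r & !s] <- 4L                     # FN
  counts <- tabulate(lab, 4L)
  structure(list(TP = counts[1], FP = counts[2], TN = counts[3],
                 FN = counts[4], label_image = lab,
                 palette = c(TP = "white", FP = "orange",
                             TN = "black", FN = "red")),
            class = "mx_confusion")
}

#' @export
print.mx_confusion <- function(x, ...) {
  cat(sprintf("<mx_confusion> TP %d  FP %d  TN %d  FN %d  (precision %.3f, recall %.3f)\n",
              x$TP, x$FP, x$TN, x$FN, precision(x), recall(x)))
  invisible(x)
}

#' Precision and recall of a pixel confusion
#'
#' `precision = TP / (TP + FP)`, the fraction of predicted aggregate pixels
#' that are correct; `recall = TP / (TP + FN)`, the fraction of true
#' aggregate pixels that are recovered. A zero denominator yields `NA`
#' (undefined), never 0.
#'
#' @param x An `mx_confusion` from [pixel_confusion()], or any list with
#'   `TP`, `FP`, `FN` counts.
#' @return A scalar in `[0, 1]`, or `NA_real_` if undefined.
#' @export
precision <- function(x) {
  if ((x$TP + x$FP) == 0) return(NA_real_)
  x$TP / (x$TP + x$FP)
}

#' @rdname precision
#' @export
recall <- function(x) {
  if ((x$TP + x$FN) == 0) return(NA_real_)
  x$TP / (x$TP + x$FN)
}

#' Render a confusion label image as RGB
#'
#' @param conf An `mx_confusion`.
#' @return An `nrow x ncol x 3` array in `[0, 1]` using the white/orange/
#'   black/red palette, suitable for `png::writePNG()`.
#' @export
confusion_rgb <- function(conf) {
  stopifnot(inherits(conf, "mx_confusion"))
  cols <- grDevices::col2rgb(conf$palette) / 255
  lab <- conf$label_image
  arr <- array(0, c(nrow(lab), ncol(lab), 3))
  for (ch in 1:3) arr[, , ch] <- matrix(cols[ch, lab], nrow(lab), ncol(lab))
  arr
}
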