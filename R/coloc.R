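#' Threshold an image to a binary mask
#'
#' `"top_percent"` keeps pixels at or above the `(100 - p)`th intensity
#' percentile (a constant image keeps every pixel -- the documented tie
#' rule). `"isodata"` iterates the classic IsoData rule, threshold = mean of
#' the two class means, on a 256-bin histogram of the image range to a
#' convergence tolerance of half a bin; it errors on a constant image.
#'
#' @param image Numeric matrix.
#' @param method `"top_percent"` or `"isodata"`.
#' @param p Percentage kept by `"top_percent"`.
#' @return Logical matrix with attributes `method`, `threshold`.
#' @export
threshold_image <- function(image, method = c("top_percent", "isodata"),
                            p = 5) {
  method <- match.arg(method)
  if (method == "top_percent") {
    thr <- quantile(image, 1 - p / 100, names = FALSE)
    mask <- image >= thr
  } else {
    rng <- range(image)
    if (diff(rng) == 0) stop("isodata thresholding needs a non-constant image")
    nbins <- 256
    binw <- diff(rng) / nbins
    thr <- mean(rng)
    repeat {
      lo <- image[image <= thr]; hi <- image[image > thr]
      if (!length(lo) || !length(hi)) break
      new <- (mean(lo) + mean(hi)) / 2
      if (abs(new - thr) < binw / 2) { thr <- new; break }
      thr <- new
    }
    mask <- image > thr
  }
  structure(mask, method = method, threshold = thr)
}

#' Label 8-connected spots in a binary mask
#'
#' Connected components under 8-connectivity (diagonal neighbours touch),
#' discarding components smaller than `min_size` pixels. Labels are
#' contiguous from 1 in raster order of each component's first pixel.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param min_size Minimum component area, pixels.
#' @return A list of class `spot_set`: `labels` (integer matrix), `table`
#'   (data frame: `label`, `row_px`, `col_px` centroids, `area`), `n_spots`.
#' @export
label_spots <- function(mask, min_size = 4) {
  mask <- mask != 0
  H <- nrow(mask); W <- ncol(mask)
  fg <- which(mask)
  labels <- matrix(0L, H, W)
  if (!length(fg)) {
    return(structure(list(labels = labels,
                          table = data.frame(label = integer(0),
                                             row_px = numeric(0),
                                             col_px = numeric(0),
                                             area = integer(0)),
                          n_spots = 0L),
                     class = "spot_set"))
  }
  pos <- match(fg, fg)  # 1..n in raster (column-major) order
  rows <- ((fg - 1L) %% H) + 1L
  cols <- ((fg - 1L) %/% H) + 1L
  # edges to 4 forward neighbours (E, SE, S, NE covers all 8-adjacency pairs)
  edge_list <- list()
  idx_of <- rep(0L, H * W); idx_of[fg] <- seq_along(fg)
  for (off in list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(-1L, 1L))) {
    nr <- rows + off[1]; nc <- cols + off[2]
    okn <- nr >= 1L & nr <= H & nc >= 1L & nc <= W
    nb <- (nc[okn] - 1L) * H + nr[okn]
    has <- idx_of[nb] > 0L
    if (any(has)) {
      edge_list[[length(edge_list) + 1L]] <-
        cbind(which(okn)[has], idx_of[nb[has]])
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edge_list)) {
    edges <- do.call(rbind, edge_list)
    g <- igraph::add_edges(g, t(edges))
  }
  comp <- igraph::components(g)$membership
  sizes <- tabulate(comp)
  keep_comp <- which(sizes >= min_size)
  # relabel kept components 1..k by first (raster-order) pixel
  firsts <- vapply(keep_comp, function(k) min(which(comp == k)), numeric(1))
  keep_comp <- keep_comp[order(firsts)]
  new_lab <- rep(0L, max(comp))
  new_lab[keep_comp] <- seq_along(keep_comp)
  lab_px <- new_lab[comp]
  labels[fg] <- lab_px
  tab <- if (length(keep_comp)) {
    data.frame(
      label = seq_along(keep_comp),
      row_px = as.numeric(tapply(rows[lab_px > 0], lab_px[lab_px > 0], mean)),
      col_px = as.numeric(tapply(cols[lab_px > 0], lab_px[lab_px > 0], mean)),
      area = as.integer(tabulate(lab_px[lab_px > 0]))
    )
  } else {
    data.frame(label = integer(0), row_px = numeric(0), col_px = numeric(0),
               area = integer(0))
  }
  structure(list(labels = labels, table = tab, n_spots = nrow(tab)),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("Spot set: %d labelled components\n", x$n_spots))
  invisible(x)
}

#' Object-based co-occurrence of two channels
#'
#' The reference channel is thresholded and its spots counted (`N_ref`); the
#' other channel is intensity-masked by the reference mask (the "AND"
#' operation), re-thresholded -- by default with the same method applied to
#' the in-mask pixel values -- labelled, and the surviving spots counted
#' (`N_joint`). The co-occurrence percentage is `100 * N_joint / N_ref`.
#' `joint_mode = "mask_and_mask"` instead intersects the two channels'
#' independent masks.
#'
#' Because joint spots are re-thresholded objects, `N_joint` is not formally
#' bounded by `N_ref`.
#'
#' @param ref_image,other_image Numeric matrices of equal shape.
#' @param method Threshold method, see [threshold_image()].
#' @param p Percentage for `"top_percent"`.
#' @param min_size Minimum spot area, pixels.
#' @param joint_mode `"rethreshold"` (default, the reference procedure) or
#'   `"mask_and_mask"`.
#' @return An object of class `cooccurrence_result`: `n_ref`, `n_joint`,
#'   `percent` (`NA` and flagged when `n_ref` is 0), `method`, `joint_mode`.
#' @export
cooccurrence_percent <- function(ref_image, other_image,
                                 method = c("top_percent", "isodata"), p = 5,
                                 min_size = 4,
                                 joint_mode = c("rethreshold", "mask_and_mask")) {
  method <- match.arg(method)
  joint_mode <- match.arg(joint_mode)
  if (!all(dim(ref_image) == dim(other_image))) {
    stop("images must have the same shape")
  }
  ref_mask <- threshold_image(ref_image, method, p)
  n_ref <- label_spots(ref_mask, min_size)$n_spots
  if (joint_mode == "mask_and_mask") {
    other_mask <- threshold_image(other_image, method, p)
    joint_mask <- ref_mask & other_mask
  } else {
    # re-threshold the AND image over the in-mask values, floored at the
    # other channel's global threshold: a joint spot must be at least as
    # bright as what counts as signal anywhere in that channel, which keeps
    # in-mask noise from being split into spurious objects when no true
    # signal is present
    inside <- other_image[ref_mask]
    joint_mask <- matrix(FALSE, nrow(ref_image), ncol(ref_image))
    if (length(inside)) {
      glob <- attr(threshold_image(other_image, method, p), "threshold")
      if (method == "top_percent") {
        # the mask is itself a quantile selection, so the only meaningful
        # re-threshold is the channel-wide quantile
        joint_mask[ref_mask] <- inside >= glob
      } else {
        sub <- if (diff(range(inside)) == 0) -Inf else {
          attr(threshold_image(matrix(inside, nrow = 1), "isodata"),
               "threshold")
        }
        joint_mask[ref_mask] <- inside > max(sub, glob)
      }
    }
  }
  n_joint <- label_spots(joint_mask, min_size)$n_spots
  pct <- if (n_ref > 0) 100 * n_joint / n_ref else NA_real_
  structure(list(n_ref = n_ref, n_joint = n_joint, percent = pct,
                 undefined = n_ref == 0, method = method,
                 joint_mode = joint_mode, p = p, min_size = min_size),
            class = "cooccurrence_result")
}

#' @export
print.cooccurrence_result <- function(x, ...) {
  if (x$undefined) {
    cat("Co-occurrence undefined: no reference spots\n")
  } else {
    cat(sprintf("Co-occurrence: %d / %d spots = %.1f%% (%s, %s)\n",
                x$n_joint, x$n_ref, x$percent, x$method, x$joint_mode))
  }
  invisible(x)
}

#' Flipped-channel chance co-occurrence control
#'
#' Mirrors the reference channel left-right and recomputes the co-occurrence
#' percentage; genuine colocalization collapses to the chance rate while
#' coincidental overlap is unaffected.
#'
#' @inheritParams cooccurrence_percent
#' @return A `cooccurrence_result` for the flipped configuration.
#' @export
flipped_channel_control <- function(ref_image, other_image,
                                    method = c("top_percent", "isodata"),
                                    p = 5, min_size = 4,
                                    joint_mode = c("rethreshold", "mask_and_mask")) {
  flipped <- ref_image[, rev(seq_len(ncol(ref_image))), drop = FALSE]
  cooccurrence_percent(flipped, other_image, method = method, p = p,
                       min_size = min_size, joint_mode = joint_mode)
}

#' Summarize co-occurrence across cells
#'
#' Cell-mean +/- SD of the per-cell percentages alongside the pooled-count
#' percentage; the two conventions can differ appreciably, so both are
#' reported.
#'
#' @param results List of `cooccurrence_result` objects (one per cell).
#' @return List: `per_cell` data frame, `mean_percent`, `sd_percent`,
#'   `pooled_percent`, `n_ref_total`, `n_joint_total`.
#' @export
summarize_cooccurrence <- function(results) {
  per <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(cell = i, n_ref = r$n_ref, n_joint = r$n_joint,
               percent = r$percent)
  }))
  ok <- !is.na(per$percent)
  list(per_cell = per,
       mean_percent = mean(per$percent[ok]),
       sd_percent = if (sum(ok) > 1) sd(per$percent[ok]) else 0,
       pooled_percent = 100 * sum(per$n_joint) / sum(per$n_ref),
       n_ref_total = sum(per$n_ref), n_joint_total = sum(per$n_joint))
}
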