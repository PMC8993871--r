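# Instance extraction: from a three-class semantic mask to per-fiber
# instances (axon component + assigned myelin annulus + border flag).

# Connected-component labeling on a logical matrix. EBImage::bwlabel is the
# 4-connected engine; 8-connectivity merges diagonally adjacent label pairs
# with a small union-find over label ids. Components are relabeled 1..K by
# row-major order of each component's first pixel so labeling is independent
# of the engine's traversal order.
label_components <- function(bin, connectivity = 8L) {
  stopifnot(is.logical(bin) || all(bin %in% c(0, 1)))
  if (!connectivity %in% c(4L, 8L))
    stop_invalid("`connectivity` must be 4 or 8")
  lab <- EBImage::imageData(EBImage::bwlabel(matrix(as.numeric(bin),
                                                    nrow(bin), ncol(bin))))
  storage.mode(lab) <- "integer"
  k <- max(lab)
  if (k == 0L) return(lab)
  if (connectivity == 8L && k > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    if (nr > 1L && nc > 1L) {
      a <- lab[-nr, -nc]; b <- lab[-1, -1]     # down-right diagonal
      c_ <- lab[-nr, -1]; d <- lab[-1, -nc]    # down-left diagonal
      pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                     cbind(as.vector(c_), as.vector(d)))
      pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
      if (nrow(pairs) > 0L) {
        parent <- seq_len(k)
        find <- function(x) { while (parent[x] != x) x <- parent[x] <<- parent[parent[x]]; x }
        for (i in seq_len(nrow(pairs))) {
          ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
        root <- vapply(seq_len(k), find, integer(1))
        lab[lab > 0L] <- root[lab[lab > 0L]]
      }
    }
  }
  relabel_row_major(lab)
}

# Relabel positive labels to 1..K ordered by the row-major position of each
# component's first pixel (R matrices are column-major, so compute the
# row-major key explicitly).
relabel_row_major <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) return(lab)
  nc <- ncol(lab)
  pos <- which(lab > 0L)
  r <- (pos - 1L) %% nrow(lab)
  c_ <- (pos - 1L) %/% nrow(lab)
  key <- r * nc + c_
  first <- tapply(key, lab[pos], min)
  ord <- ids[order(first[as.character(ids)])]
  map <- integer(max(ids)); map[ord] <- seq_along(ord)
  lab[pos] <- map[lab[pos]]
  lab
}

#' Label axon connected components
#'
#' Connected components of axon pixels under the chosen connectivity
#' (default 8, suited to near-circular objects rasterized with diagonal
#' steps); components smaller than `min_axon_px` are discarded as noise.
#' Surviving components are labeled 1..K in row-major order of their first
#' pixel.
#'
#' @param mask A [semantic_mask].
#' @param min_axon_px Minimum component area in pixels (default 5, about a
#'   0.25 um equivalent diameter at 0.1 um/px).
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix of axon labels (0 = not an axon).
#' @export
label_axons <- function(mask, min_axon_px = 5L, connectivity = 8L) {
  stopifnot(inherits(mask, "semantic_mask"))
  lab <- label_components(mask$labels == MASK_AXON, connectivity)
  k <- max(lab)
  if (k > 0L && min_axon_px > 1L) {
    sizes <- tabulate(lab, nbins = k)
    drop <- which(sizes < min_axon_px)
    if (length(drop) > 0L) {
      lab[lab %in% drop] <- 0L
      lab <- relabel_row_major(lab)
    }
  }
  lab
}

#' Assign myelin pixels to their nearest axon component
#'
#' Each myelin pixel belonging to a myelin component (8-connected) that
#' touches at least one axon component is assigned to the axon component at
#' the smallest Euclidean distance (exact, via one distance transform per
#' component; ties go to the lower fiber id). Myelin components touching no
#' axon remain orphan and never enter fiber morphometry.
#'
#' @param mask A [semantic_mask].
#' @param axon_labels Integer label matrix from [label_axons], derived from
#'   the same mask.
#' @return List with `myelin_labels` (integer matrix, 0 = unassigned) and
#'   `orphan` (logical matrix marking orphan myelin pixels).
#' @export
partition_myelin <- function(mask, axon_labels) {
  stopifnot(inherits(mask, "semantic_mask"))
  assert_same_shape(mask$labels, axon_labels, "mask and axon labels")
  myelin <- mask$labels == MASK_MYELIN
  k <- max(axon_labels)
  out <- matrix(0L, nrow(myelin), ncol(myelin))
  if (!any(myelin)) return(list(myelin_labels = out, orphan = myelin))
  if (k == 0L) return(list(myelin_labels = out, orphan = myelin))
  mcomp <- label_components(myelin, connectivity = 8L)
  # myelin components adjacent (8-neighborhood) to any axon pixel
  ax_dil <- EBImage::imageData(EBImage::dilate(
    EBImage::Image((axon_labels > 0L) * 1),
    EBImage::makeBrush(3L, shape = "box"))) > 0
  touching <- sort(unique(mcomp[ax_dil & mcomp > 0L]))
  assignable <- myelin & (mcomp %in% touching)
  orphan <- myelin & !assignable
  if (any(assignable)) {
    if (k == 1L) {
      out[assignable] <- 1L
    } else {
      # Exact nearest-component assignment, one distance transform per
      # component but restricted to its bounding box padded by D, the
      # largest distance any assignable pixel has to its nearest component
      # (from one global distance map). A pixel outside that window is
      # provably closer to some other component, so the crop is lossless.
      nr <- nrow(myelin); nc <- ncol(myelin)
      d_any <- EBImage::imageData(EBImage::distmap(
        EBImage::Image((axon_labels == 0L) * 1)))
      pad <- ceiling(max(d_any[assignable])) + 2L
      best <- matrix(Inf, nr, nc)
      bestlab <- out
      for (id in seq_len(k)) {
        pos <- which(axon_labels == id, arr.ind = TRUE)
        ri <- max(1L, min(pos[, 1]) - pad):min(nr, max(pos[, 1]) + pad)
        ci <- max(1L, min(pos[, 2]) - pad):min(nc, max(pos[, 2]) + pad)
        d <- EBImage::imageData(EBImage::distmap(
          EBImage::Image((axon_labels[ri, ci, drop = FALSE] != id) * 1)))
        upd <- assignable[ri, ci, drop = FALSE] &
          (d < best[ri, ci, drop = FALSE])  # strict: ties keep the lower id
        bb <- best[ri, ci, drop = FALSE]; bl <- bestlab[ri, ci, drop = FALSE]
        bb[upd] <- d[upd]; bl[upd] <- id
        best[ri, ci] <- bb; bestlab[ri, ci] <- bl
      }
      out[assignable] <- bestlab[assignable]
    }
  }
  list(myelin_labels = out, orphan = orphan)
}

#' Build per-fiber instances from a semantic mask
#'
#' Labels axon components, apportions myelin pixels to them, and flags fibers
#' touching the image border (any axon or assigned myelin pixel in the first
#' or last row or column): a fiber cropped by the region of interest has a
#' corrupted thickness and must be excludable.
#'
#' @inheritParams label_axons
#' @return A `fiber_set`: list with `axon_labels` and `myelin_labels`
#'   (integer matrices), `fibers` (tibble: `fiber_id`, `axon_px`, `myelin_px`,
#'   `touches_border`), `orphan` (logical matrix of orphan myelin pixels),
#'   `source_shape`, `pixel_size`.
#' @export
build_fiber_set <- function(mask, min_axon_px = 5L, connectivity = 8L) {
  stopifnot(inherits(mask, "semantic_mask"))
  ax <- label_axons(mask, min_axon_px, connectivity)
  pm <- partition_myelin(mask, ax)
  k <- max(ax)
  shape <- dim(mask$labels)
  if (k == 0L) {
    fibers <- tibble::tibble(fiber_id = integer(), axon_px = integer(),
                             myelin_px = integer(), touches_border = logical())
  } else {
    axon_px <- tabulate(ax, nbins = k)
    myelin_px <- tabulate(pm$myelin_labels, nbins = k)
    border <- matrix(FALSE, shape[1], shape[2])
    border[c(1L, shape[1]), ] <- TRUE
    border[, c(1L, shape[2])] <- TRUE
    on_border <- union(ax[border & ax > 0L],
                       pm$myelin_labels[border & pm$myelin_labels > 0L])
    fibers <- tibble::tibble(
      fiber_id = seq_len(k),
      axon_px = axon_px,
      myelin_px = myelin_px,
      touches_border = seq_len(k) %in% on_border)
  }
  structure(list(axon_labels = ax, myelin_labels = pm$myelin_labels,
                 fibers = fibers, orphan = pm$orphan,
                 source_shape = shape, pixel_size = mask$pixel_size),
            class = "fiber_set")
}

#' @export
print.fiber_set <- function(x, ...) {
  cat(sprintf("<fiber_set> %d fibers (%d on border), %d orphan myelin px, %d x %d px @ %g um/px\n",
              nrow(x$fibers), sum(x$fibers$touches_border), sum(x$orphan),
              x$source_shape[1], x$source_shape[2], x$pixel_size))
  invisible(x)
}

#' Drop fibers touching the region-of-interest border
#'
#' Returns the fiber set restricted to fibers with `touches_border = FALSE`.
#' Fiber ids are preserved (not renumbered) and the orphan myelin set is
#' unchanged, so excluded fibers remain traceable against the full set.
#'
#' @param fs A `fiber_set`.
#' @return A `fiber_set` containing only interior fibers.
#' @export
exclude_border_fibers <- function(fs) {
  stopifnot(inherits(fs, "fiber_set"))
  drop <- fs$fibers$fiber_id[fs$fibers$touches_border]
  if (length(drop) > 0L) {
    fs$axon_labels[fs$axon_labels %in% drop] <- 0L
    fs$myelin_labels[fs$myelin_labels %in% drop] <- 0L
    fs$fibers <- fs$fibers[!fs$fibers$touches_border, , drop = FALSE]
  }
  fs
}
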