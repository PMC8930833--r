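# Vessel segmentation and centerline extraction: Otsu threshold of the
# temporal-mean image, morphological closing, connected components above a
# minimum area, Zhang-Suen skeletonization and the longest skeleton path.

# Zhang-Suen binary thinning, vectorized over the whole image.
thin_mask <- function(mask) {
  img <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  # neighbour order P2..P9: N, NE, E, SE, S, SW, W, NW
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- lapply(offs, function(o) shift_mat(img, o[1], o[2]))
      bsum <- Reduce(`+`, nb)
      a <- matrix(0L, nrow(img), ncol(img))
      for (k in 1:8) {
        nxt <- nb[[if (k == 8) 1 else k + 1]]
        a <- a + (nb[[k]] == 0L & nxt == 1L)
      }
      if (step == 1) {
        cond <- nb[[1]] * nb[[3]] * nb[[5]] == 0L & nb[[3]] * nb[[5]] * nb[[7]] == 0L
      } else {
        cond <- nb[[1]] * nb[[3]] * nb[[7]] == 0L & nb[[1]] * nb[[5]] * nb[[7]] == 0L
      }
      del <- img == 1L & bsum >= 2 & bsum <= 6 & a == 1L & cond
      if (any(del)) {
        img[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img == 1L
}

# Longest geodesic path through a skeleton, as ordered (x, y) coordinates.
skeleton_longest_path <- function(skel) {
  idx <- which(skel, arr.ind = TRUE)  # (row, col) = (y, x)
  n <- nrow(idx)
  if (n == 0) return(NULL)
  if (n == 1) return(cbind(x = idx[, 2], y = idx[, 1]))
  key <- (idx[, 2] - 1) * nrow(skel) + idx[, 1]
  lookup <- integer(0)
  lookup[as.character(key)] <- seq_len(n)
  edges <- NULL
  wts <- NULL
  for (o in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    nb_key <- (idx[, 2] - 1 + o[2]) * nrow(skel) + idx[, 1] + o[1]
    j <- lookup[as.character(nb_key)]
    ok <- !is.na(j) &
      idx[, 1] + o[1] >= 1 & idx[, 1] + o[1] <= nrow(skel) &
      idx[, 2] + o[2] >= 1 & idx[, 2] + o[2] <= ncol(skel)
    if (any(ok)) {
      edges <- rbind(edges, cbind(seq_len(n)[ok], j[ok]))
      wts <- c(wts, rep(sqrt(sum(o^2)), sum(ok)))
    }
  }
  if (is.null(edges)) return(cbind(x = idx[1, 2], y = idx[1, 1]))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- wts
  path <- as.integer(igraph::get_diameter(g))
  cbind(x = idx[path, 2], y = idx[path, 1])
}

# Unit tangents along a polyline, smoothed over +/- `half_win` points by a
# local principal-direction fit with sign continuity.
smoothed_tangents <- function(pts, half_win = 5) {
  n <- nrow(pts)
  tg <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    lo <- max(1, i - half_win); hi <- min(n, i + half_win)
    seg <- pts[lo:hi, , drop = FALSE]
    if (nrow(seg) < 2) {
      tg[i, ] <- c(1, 0)
      next
    }
    cc <- sweep(seg, 2, colMeans(seg))
    v <- eigen(crossprod(cc), symmetric = TRUE)$vectors[, 1]
    # orient along the direction of travel
    dir <- pts[hi, ] - pts[lo, ]
    if (sum(v * dir) < 0) v <- -v
    tg[i, ] <- v / sqrt(sum(v^2))
  }
  tg
}

#' Segment vessels and extract centerlines
#'
#' Thresholds the temporal-mean image (Otsu), applies morphological closing,
#' drops connected components below a minimum area, skeletonizes each
#' remaining component and returns the longest skeleton path per component
#' with smoothed unit tangents.
#'
#' @param stack A standardized [video_stack()] (green channel).
#' @param min_area Minimum component area in square pixels.
#' @param brush_size Diameter of the disc brush used for closing (odd).
#' @return List of candidates, each a list with `mask` (logical matrix) and
#'   `centerline` (list with `points`, an n x 2 (x, y) matrix, and
#'   `tangents`).
#' @export
segment_vessels <- function(stack, min_area = 200, brush_size = 5) {
  stopifnot(inherits(stack, "VideoStack"))
  avg <- rowMeans(stack$frames, dims = 2)
  img <- avg / 255
  if (diff(range(img)) < 1e-6) stopf("no usable arteriole")
  thr <- EBImage::otsu(EBImage::Image(img))
  mask <- img > thr
  mask <- EBImage::closing(mask, EBImage::makeBrush(brush_size, "disc")) > 0
  labels <- EBImage::bwlabel(mask)
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= min_area)
  if (length(keep) == 0) stopf("no usable arteriole")
  out <- lapply(keep, function(k) {
    comp <- labels == k
    skel <- thin_mask(comp)
    pts <- skeleton_longest_path(skel)
    if (is.null(pts) || nrow(pts) < 2) return(NULL)
    list(mask = comp,
         centerline = list(points = pts, tangents = smoothed_tangents(pts)))
  })
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0) stopf("no usable arteriole")
  out
}

#' Randomly choose one arteriole among candidates
#'
#' When segmentation finds more than one usable arteriole, one is chosen
#' uniformly at random, reproducibly for a given seed.
#'
#' @param candidates List returned by [segment_vessels()].
#' @param seed Integer seed driving the choice.
#' @return A single candidate (unchanged if only one).
#' @export
select_arteriole <- function(candidates, seed = 1L) {
  if (length(candidates) == 0) stopf("no candidates to select from")
  if (length(candidates) == 1) return(candidates[[1]])
  i <- with_seed(seed, sample.int(length(candidates), 1))
  candidates[[i]]
}
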