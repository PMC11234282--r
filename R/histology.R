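#' Threshold-based marker segmentation
#'
#' Segments fluorescent marker pixels inside a region of interest by
#' intensity thresholding: Otsu's method computed on the ROI histogram
#' (default) or a fixed level. The threshold actually applied is recorded
#' as an attribute. Area fraction downstream is invariant to a global
#' intensity rescaling under Otsu, while mean intensity scales linearly.
#'
#' @param image Numeric matrix (intensity raster, a.u.).
#' @param roi_mask Logical matrix; segmentation is restricted to it.
#' @param method `"otsu"` or `"fixed"`.
#' @param level Threshold (a.u.) for `method = "fixed"`.
#' @return Logical matrix of segmented pixels (subset of `roi_mask`) with
#'   attribute `threshold`.
#' @export
segment_marker <- function(image, roi_mask = NULL,
                           method = c("otsu", "fixed"), level = NULL) {
  method <- match.arg(method)
  if (is.null(roi_mask)) roi_mask <- array(TRUE, dim(image))
  stopifnot(identical(dim(image), dim(roi_mask)), any(roi_mask))
  vals <- image[roi_mask]
  if (method == "otsu") {
    rng <- range(vals)
    if (diff(rng) == 0) stop("constant image: Otsu threshold undefined")
    scaled <- (vals - rng[1]) / diff(rng)
    th01 <- EBImage::otsu(matrix(scaled, ncol = 1), range = c(0, 1),
                          levels = 256L)
    thr <- rng[1] + th01 * diff(rng)
  } else {
    if (is.null(level)) stop("method = 'fixed' requires a level")
    thr <- level
  }
  mask <- roi_mask & image > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Area fraction and mean intensity of a segmented marker in an ROI
#'
#' @param image Numeric matrix.
#' @param mask Logical matrix of segmented pixels (must lie inside the ROI).
#' @param roi_mask Logical matrix.
#' @param roi_id,marker Optional labels carried into the result.
#' @return A one-row data.frame: `roi_id`, `marker`, `area_fraction` (\%),
#'   `mean_intensity` (a.u.; 0 with `empty_mask = TRUE` when nothing was
#'   segmented), `n_roi`, `n_mask`.
#' @export
quantify_roi <- function(image, mask, roi_mask, roi_id = NA_character_,
                         marker = NA_character_) {
  stopifnot(any(roi_mask))
  if (any(mask & !roi_mask)) stop("mask must be a subset of roi_mask")
  n_roi <- sum(roi_mask); n_mask <- sum(mask)
  data.frame(roi_id = roi_id, marker = marker,
             area_fraction = 100 * n_mask / n_roi,
             mean_intensity = if (n_mask > 0) mean(image[mask]) else 0,
             empty_mask = n_mask == 0,
             n_roi = n_roi, n_mask = n_mask,
             stringsAsFactors = FALSE)
}

# Zhang-Suen thinning of a logical matrix to a 1-pixel skeleton.
skeletonize <- function(mask) {
  m <- mask
  m[is.na(m)] <- FALSE
  pad <- function(x) rbind(FALSE, cbind(FALSE, x, FALSE), FALSE)
  shift <- function(x, dr, dc) {
    nr <- nrow(x); nc <- ncol(x)
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  m <- pad(m)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours p2..p9 clockwise from north
      p2 <- shift(m, 1, 0);  p3 <- shift(m, 1, -1)
      p4 <- shift(m, 0, -1); p5 <- shift(m, -1, -1)
      p6 <- shift(m, -1, 0); p7 <- shift(m, -1, 1)
      p8 <- shift(m, 0, 1);  p9 <- shift(m, 1, 1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (sub == 1) {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m[2:(nrow(m) - 1), 2:(ncol(m) - 1)]
}

# Crossing number: 0->1 transitions around each pixel's 8-neighbour ring.
.crossing_number <- function(m) {
  p <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)
  sh <- function(dr, dc) {
    nr <- nrow(p); nc <- ncol(p)
    p[(2 - dr):(nr - 1 - dr), (2 - dc):(nc - 1 - dc)]
  }
  # ring order: N, NE, E, SE, S, SW, W, NW and back to N
  ring <- list(sh(1, 0), sh(1, 1), sh(0, 1), sh(-1, 1),
               sh(-1, 0), sh(-1, -1), sh(0, -1), sh(1, -1))
  a <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(8)) {
    j <- if (i == 8) 1L else i + 1L
    a <- a + (!ring[[i]] & ring[[j]])
  }
  a
}

# 8-connected component labelling (skeleton paths step diagonally, so
# 4-connected labelling would split them at every staircase step).
.label8 <- function(mask) {
  dm <- dim(mask)
  lab <- matrix(0L, dm[1], dm[2])
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      i <- queue[length(queue)]; queue <- queue[-length(queue)]
      r <- (i - 1L) %% dm[1] + 1L; cc <- (i - 1L) %/% dm[1] + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr < 1 || rr > dm[1] || c2 < 1 || c2 > dm[2]) next
        j <- rr + (c2 - 1L) * dm[1]
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# 8-connected neighbour count on a logical matrix.
.neighbour_count <- function(m) {
  p <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)
  n <- p[1:(nrow(p) - 2), 2:(ncol(p) - 1)] + p[3:nrow(p), 2:(ncol(p) - 1)] +
    p[2:(nrow(p) - 1), 1:(ncol(p) - 2)] + p[2:(nrow(p) - 1), 3:ncol(p)] +
    p[1:(nrow(p) - 2), 1:(ncol(p) - 2)] + p[1:(nrow(p) - 2), 3:ncol(p)] +
    p[3:nrow(p), 1:(ncol(p) - 2)] + p[3:nrow(p), 3:ncol(p)]
  n
}

# Main centerline of a skeleton component: the weighted (1 / sqrt(2))
# shortest path between its two most distant pixels, found by Dijkstra from
# an endpoint (or any pixel for cycles). Small bumps off the main chain are
# left out. Returns row indices into px, in path order, or NULL for
# components with no usable path.
.order_path <- function(px) {
  n <- nrow(px)
  if (n == 1) return(1L)
  adj <- lapply(seq_len(n), function(i) {
    which(abs(px[, 1] - px[i, 1]) <= 1 & abs(px[, 2] - px[i, 2]) <= 1 &
            seq_len(n) != i)
  })
  dijkstra <- function(src) {
    dist <- rep(Inf, n); prev <- rep(NA_integer_, n)
    dist[src] <- 0
    done <- logical(n)
    for (it in seq_len(n)) {
      u <- which.min(ifelse(done, Inf, dist))
      if (!is.finite(dist[u])) break
      done[u] <- TRUE
      for (v in adj[[u]]) {
        w <- sqrt(sum((px[u, ] - px[v, ])^2))
        if (dist[u] + w < dist[v]) { dist[v] <- dist[u] + w; prev[v] <- u }
      }
    }
    list(dist = dist, prev = prev)
  }
  deg <- lengths(adj)
  start <- if (any(deg == 1)) which(deg == 1)[1] else 1L
  d1 <- dijkstra(start)
  far1 <- which.max(ifelse(is.finite(d1$dist), d1$dist, -1))
  d2 <- dijkstra(far1)
  far2 <- which.max(ifelse(is.finite(d2$dist), d2$dist, -1))
  if (far1 == far2) return(NULL)
  path <- far2; v <- far2
  while (!is.na(d2$prev[v])) { v <- d2$prev[v]; path <- c(v, path) }
  path
}

#' Vessel morphometry from a binary mask
#'
#' Skeletonises each tubular component (Zhang-Suen thinning), splits the
#' skeleton at branch points, and measures each resulting segment: path
#' length (sum of centerline step lengths, with the junction pixel counted
#' into the length of every incident segment), chord length (endpoint
#' distance), mean diameter (twice the half-pixel-corrected mean distance-transform
#' value along the centerline, junctions excluded) and tortuosity
#' (path/chord, >= 1). Segments shorter than 3 centerline pixels are
#' discarded and counted.
#'
#' @param mask Logical matrix of vessel pixels.
#' @param pixel_size Pixel edge length in micrometres.
#' @return List: `segments` (data.frame with `path_length_um`,
#'   `chord_length_um`, `mean_diameter_um`, `tortuosity`, `n_pixels`),
#'   `summary` (means across segments), `n_discarded`.
#' @export
vessel_morphometry <- function(mask, pixel_size = 1) {
  stopifnot(any(mask))
  skel <- skeletonize(mask)
  dmap <- as.matrix(EBImage::distmap(matrix(as.numeric(mask), nrow(mask))))
  # junctions are pixels whose 8-neighbourhood splits into >= 3 distinct
  # branches (crossing number), not merely >= 3 neighbours: staircase
  # corners on smooth curves have 3 neighbours but only 2 branches
  branch <- skel & .crossing_number(skel) >= 3
  body <- skel & !branch
  lab <- .label8(body)
  segs <- list(); discarded <- 0L
  bpx <- which(branch, arr.ind = TRUE)
  for (id in seq_len(max(lab))) {
    px <- which(lab == id, arr.ind = TRUE)
    if (nrow(px) < 3) { discarded <- discarded + 1L; next }
    ord <- .order_path(px)
    if (is.null(ord)) { discarded <- discarded + 1L; next }
    path <- px[ord, , drop = FALSE]
    steps <- sqrt(rowSums((path[-1, , drop = FALSE] -
                             path[-nrow(path), , drop = FALSE])^2))
    plen <- sum(steps)
    ends <- path[c(1, nrow(path)), , drop = FALSE]
    # junction pixels adjacent to either end extend the path length
    chord_pts <- ends
    for (e in 1:2) {
      if (nrow(bpx) == 0) break
      d <- sqrt((bpx[, 1] - ends[e, 1])^2 + (bpx[, 2] - ends[e, 2])^2)
      j <- which(d <= sqrt(2) + 1e-9)
      if (length(j)) {
        jj <- j[which.min(d[j])]
        plen <- plen + d[jj]
        chord_pts[e, ] <- bpx[jj, ]
      }
    }
    chord <- sqrt(sum((chord_pts[1, ] - chord_pts[2, ])^2))
    # distmap measures to the first background pixel; half-pixel correction
    # recovers the drawn width (2r + 1 pixels for an ideal tube of radius r)
    diam <- 2 * (mean(dmap[path]) - 0.5)
    segs[[length(segs) + 1L]] <- data.frame(
      path_length_um = plen * pixel_size,
      chord_length_um = chord * pixel_size,
      mean_diameter_um = diam * pixel_size,
      tortuosity = if (chord > 0) plen / chord else NA_real_,
      n_pixels = nrow(path))
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(path_length_um = numeric(), chord_length_um = numeric(),
               mean_diameter_um = numeric(), tortuosity = numeric(),
               n_pixels = integer())
  list(segments = segments,
       summary = data.frame(
         mean_length_um = mean(segments$path_length_um),
         mean_diameter_um = mean(segments$mean_diameter_um),
         mean_tortuosity = mean(segments$tortuosity, na.rm = TRUE),
         n_segments = nrow(segments)),
       n_discarded = discarded)
}

#' Count red-blood-cell extravasation sites
#'
#' Groups RBC centroids by single-linkage clustering at `site_radius` and
#' counts clusters containing at least `min_count` cells (default 5, the
#' "site with at least 5 RBCs" rule).
#'
#' @param centroids n x 2 matrix of coordinates (micrometres).
#' @param site_radius Linkage distance, micrometres (default 50).
#' @param min_count Minimum cells per site (default 5).
#' @return Integer number of sites.
#' @export
count_rbc_sites <- function(centroids, site_radius = 50, min_count = 5L) {
  if (site_radius < 0) stop("site_radius must be >= 0")
  if (min_count < 1) stop("min_count must be >= 1")
  n <- if (is.null(nrow(centroids))) 0L else nrow(centroids)
  if (n == 0) return(0L)
  if (n == 1) return(as.integer(min_count <= 1))
  cl <- stats::cutree(stats::hclust(stats::dist(centroids), method = "single"),
                      h = site_radius)
  sum(tabulate(cl) >= min_count)
}
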