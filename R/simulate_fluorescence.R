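#' Simulate a fluorescence microscopy image with known ground truth
#'
#' Renders a single-channel field containing glial-cell-like blobs (a disk
#' soma with radiating processes), tubular vessels following a polyline
#' centerline with constant radius, and point-like red-blood-cell clusters,
#' over a Gaussian background. Truth masks (per object class), the vessel
#' centerlines and the RBC centroids are returned for oracle comparison.
#'
#' @param shape Integer pair (rows, cols) in pixels.
#' @param objects List of objects; each is a list with `kind` one of
#'   `"cell"`, `"vessel"`, `"rbc"`, an `intensity` (a.u.), and a geometry:
#'   cells take `center` (row, col), `radius` and optional `n_arms`,
#'   `arm_length`; vessels take `path` (n x 2 matrix of row/col vertices)
#'   and `radius`; rbc take `points` (n x 2 matrix) and optional `radius`
#'   (default 1).
#' @param background_sd Gaussian background noise SD (a.u.).
#' @param background_level Mean background (a.u., default 0).
#' @param seed Integer seed.
#' @return List: `image` (matrix), `truth` (list of logical masks
#'   `cell_mask`, `vessel_mask`, `rbc_mask`), `centerlines` (list of n x 2
#'   matrices, one per vessel), `rbc_centroids` (matrix).
#' @export
simulate_fluorescence <- function(shape, objects = list(), background_sd = 0,
                                  background_level = 0, seed = 1L) {
  stopifnot(length(shape) == 2, all(shape >= 4), background_sd >= 0)
  nr <- shape[1]; nc <- shape[2]
  img <- matrix(background_level, nr, nc)
  cell_mask <- matrix(FALSE, nr, nc)
  vessel_mask <- matrix(FALSE, nr, nc)
  rbc_mask <- matrix(FALSE, nr, nc)
  centerlines <- list()
  rbc_centroids <- NULL
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

  inside <- function(pts) all(pts[, 1] >= 1 & pts[, 1] <= nr &
                                pts[, 2] >= 1 & pts[, 2] <= nc)

  for (ob in objects) {
    kind <- match.arg(ob$kind, c("cell", "vessel", "rbc"))
    if (kind == "cell") {
      ctr <- ob$center; r <- ob$radius
      if (!inside(matrix(ctr, 1))) stop("cell center outside canvas")
      m <- (rows - ctr[1])^2 + (cols - ctr[2])^2 <= r^2
      n_arms <- if (is.null(ob$n_arms)) 0L else ob$n_arms
      if (n_arms > 0) {
        al <- if (is.null(ob$arm_length)) 2 * r else ob$arm_length
        for (a in seq_len(n_arms)) {
          th <- 2 * pi * (a - 1) / n_arms
          t_seq <- seq(0, al, by = 0.5)
          pr <- pmin(pmax(round(ctr[1] + t_seq * sin(th)), 1), nr)
          pc <- pmin(pmax(round(ctr[2] + t_seq * cos(th)), 1), nc)
          m[cbind(pr, pc)] <- TRUE
        }
      }
      cell_mask <- cell_mask | m
      img[m] <- img[m] + ob$intensity
    } else if (kind == "vessel") {
      path <- ob$path
      if (!inside(path)) stop("vessel path outside canvas")
      d2 <- matrix(Inf, nr, nc)
      for (s in seq_len(nrow(path) - 1)) {
        a <- path[s, ]; b <- path[s + 1, ]
        ab <- b - a; len2 <- sum(ab^2)
        t <- if (len2 == 0) 0 else
          pmin(pmax(((rows - a[1]) * ab[1] + (cols - a[2]) * ab[2]) / len2, 0), 1)
        d2 <- pmin(d2, (rows - (a[1] + t * ab[1]))^2 +
                     (cols - (a[2] + t * ab[2]))^2)
      }
      m <- d2 <= ob$radius^2
      vessel_mask <- vessel_mask | m
      img[m] <- img[m] + ob$intensity
      centerlines[[length(centerlines) + 1L]] <- path
    } else {
      pts <- ob$points
      if (!inside(pts)) stop("rbc point outside canvas")
      r <- if (is.null(ob$radius)) 1 else ob$radius
      for (i in seq_len(nrow(pts))) {
        m <- (rows - pts[i, 1])^2 + (cols - pts[i, 2])^2 <= r^2
        rbc_mask <- rbc_mask | m
        img[m] <- img[m] + ob$intensity
      }
      rbc_centroids <- rbind(rbc_centroids, pts)
    }
  }
  if (background_sd > 0)
    img <- img + withr::with_seed(seed,
                                  matrix(stats::rnorm(nr * nc, sd = background_sd),
                                         nr, nc))
  list(image = img,
       truth = list(cell_mask = cell_mask, vessel_mask = vessel_mask,
                    rbc_mask = rbc_mask),
       centerlines = centerlines,
       rbc_centroids = rbc_centroids)
}

#' Write / read a fluorescence image as 16-bit TIFF
#'
#' Intensities are scaled by `scale` into the 16-bit range on write and
#' rescaled on read.
#'
#' @param image Numeric matrix.
#' @param path Output file.
#' @param scale a.u.-per-unit scaling to the 0..1 TIFF range.
#' @export
write_fluorescence_tiff <- function(image, path, scale = max(image, 1)) {
  tiff::writeTIFF(pmin(pmax(image / scale, 0), 1), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_fluorescence_tiff
#' @export
read_fluorescence_tiff <- function(path, scale = 1) {
  as.matrix(tiff::readTIFF(path)) * scale
}
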