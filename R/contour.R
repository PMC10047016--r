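#' Rasterize a contour polygon to a pixel mask
#'
#' Marks every pixel whose center lies inside or on the polygon, using the
#' even-odd (ray crossing) rule with boundary points included. Pixel centers
#' sit at integer 0-based coordinates: mask entry `[i, j]` (1-based matrix
#' indices) corresponds to the point `(x = j - 1, y = i - 1)`.
#'
#' @param contour data.frame or matrix with columns `x`, `y` (0-based pixel
#'   coordinates); an open or closed vertex list of a simple polygon
#' @param shape image dimensions `c(nrow, ncol)`
#' @return logical matrix of dimension `shape`
#' @export
rasterize_contour <- function(contour, shape) {
  contour <- as.data.frame(contour)
  stopifnot(all(c("x", "y") %in% names(contour)), length(shape) == 2L)
  vx <- as.numeric(contour$x)
  vy <- as.numeric(contour$y)
  # drop an explicit closing vertex
  nv <- length(vx)
  if (nv >= 2 && vx[1] == vx[nv] && vy[1] == vy[nv]) {
    vx <- vx[-nv]; vy <- vy[-nv]; nv <- nv - 1L
  }
  # drop consecutive duplicate vertices (zero-length edges), which arise
  # when contours are clamped to the image bounds
  dup <- vx == c(vx[-1], vx[1]) & vy == c(vy[-1], vy[1])
  if (any(dup)) {
    vx <- vx[!dup]; vy <- vy[!dup]; nv <- length(vx)
  }
  if (nv < 3L)
    stop("degenerate polygon: fewer than 3 distinct vertices", call. = FALSE)
  area2 <- abs(sum(vx * c(vy[-1], vy[1]) - c(vx[-1], vx[1]) * vy))
  if (area2 == 0)
    stop("degenerate polygon: zero area", call. = FALSE)

  nr <- shape[1]; nc <- shape[2]
  eps <- 1e-9
  # pixels outside the polygon's bounding box (with an eps margin) cannot be
  # inside or on it; restrict the per-edge work to the box
  cset <- max(0L, floor(min(vx) - eps)):min(nc - 1L, ceiling(max(vx) + eps))
  rset <- max(0L, floor(min(vy) - eps)):min(nr - 1L, ceiling(max(vy) + eps))
  px <- rep(cset, each = length(rset))    # column-major, matches matrix()
  py <- rep(rset, times = length(cset))
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    # even-odd crossing test against edge (i, j)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    # boundary inclusion: point within eps of the segment
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    t <- pmin(pmax(((px - xi) * dx + (py - yi) * dy) / len2, 0), 1)
    d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
    on_edge <- on_edge | d2 <= eps^2
    j <- i
  }
  mask <- matrix(FALSE, nr, nc)
  mask[cbind(rep(rset, times = length(cset)) + 1L,
             rep(cset, each = length(rset)) + 1L)] <- inside | on_edge
  mask
}
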