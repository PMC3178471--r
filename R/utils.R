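# internal geometry helpers shared across modules

# world (mm) <-> 1-based voxel index; voxel centres sit at
# origin + (index - 1) * spacing
world_to_index <- function(p, spacing, origin) {
  (p - origin) / spacing + 1
}

index_to_world <- function(idx, spacing, origin) {
  origin + (idx - 1) * spacing
}

# linear index (1-based, column-major) of an integer voxel triple
linear_index <- function(ijk, dims) {
  ijk[1] + dims[1] * ((ijk[2] - 1) + dims[2] * (ijk[3] - 1))
}

linear_to_ijk <- function(lin, dims) {
  lin0 <- lin - 1
  k <- lin0 %/% (dims[1] * dims[2])
  rem <- lin0 - k * dims[1] * dims[2]
  j <- rem %/% dims[1]
  i <- rem - j * dims[1]
  cbind(i + 1, j + 1, k + 1)
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                    pts[-nrow(pts), , drop = FALSE])^2)))
}

cumulative_arc <- function(pts) {
  if (nrow(pts) < 2) return(0)
  c(0, cumsum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                            pts[-nrow(pts), , drop = FALSE])^2))))
}

# resample a polyline at (approximately) uniform arc-length step
resample_polyline <- function(pts, step) {
  s <- cumulative_arc(pts)
  total <- s[length(s)]
  if (total <= 0) return(pts[1, , drop = FALSE])
  ns <- max(2L, ceiling(total / step) + 1L)
  ss <- seq(0, total, length.out = ns)
  out <- matrix(NA_real_, ns, 3)
  for (d in 1:3) out[, d] <- approx(s, pts[, d], xout = ss)$y
  out
}

# centred moving average with shrinking windows at the ends, so the
# endpoints themselves are preserved exactly
smooth_polyline <- function(pts, window = 5L) {
  n <- nrow(pts)
  if (n < 3 || window < 3) return(pts)
  half <- window %/% 2L
  out <- pts
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    if (h == 0L) next
    out[i, ] <- colMeans(pts[(i - h):(i + h), , drop = FALSE])
  }
  out
}

# row-wise orthonormal bases of the planes perpendicular to a matrix of
# tangent vectors; returns list of n x 3 matrices e1, e2
plane_bases <- function(tang) {
  nrm <- sqrt(rowSums(tang^2))
  nrm[nrm == 0] <- 1
  t1 <- tang / nrm
  ref <- cbind(as.numeric(abs(t1[, 1]) < 0.9), 0,
               as.numeric(abs(t1[, 1]) >= 0.9))
  e1 <- ref - t1 * rowSums(ref * t1)
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(t1[, 2] * e1[, 3] - t1[, 3] * e1[, 2],
              t1[, 3] * e1[, 1] - t1[, 1] * e1[, 3],
              t1[, 1] * e1[, 2] - t1[, 2] * e1[, 1])
  list(e1 = e1, e2 = e2)
}

# orthonormal basis of the plane perpendicular to a tangent vector
plane_basis <- function(tangent) {
  t1 <- tangent / sqrt(sum(tangent^2))
  ref <- if (abs(t1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * t1) * t1
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(t1[2] * e1[3] - t1[3] * e1[2],
          t1[3] * e1[1] - t1[1] * e1[3],
          t1[1] * e1[2] - t1[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' @importFrom stats approx
interp_at <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 1)$y
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
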