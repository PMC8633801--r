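# geometric fixtures and independent R oracles used across test files

# unit icosphere (vertices on the unit sphere), optionally subdivided
icosphere <- function(subdiv = 1L) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid <- new.env()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(mid[[key]])) return(mid[[key]])
      p <- (V[i, ] + V[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      V <<- rbind(V, p)
      mid[[key]] <- nrow(V)
      nrow(V)
    }
    Fn <- matrix(0L, 0, 3)
    for (k in seq_len(nrow(F))) {
      a <- F[k, 1]; b <- F[k, 2]; cc <- F[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      Fn <- rbind(Fn, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    F <- Fn
  }
  list(V = V, F = F)
}

# point-to-segment distance, independent of the compiled implementation
r_point_seg_dist <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- min(max(t, 0), 1)
  sqrt(sum((p - (a + t * ab))^2))
}

# point-in-triangle test through barycentric coordinates (3-D, coplanar)
r_in_triangle <- function(p, a, b, cc, strict = TRUE) {
  v0 <- b - a; v1 <- cc - a; v2 <- p - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  u <- 1 - v - w
  # also require the point to lie in the triangle plane
  n <- c(v0[2] * v1[3] - v0[3] * v1[2], v0[3] * v1[1] - v0[1] * v1[3],
         v0[1] * v1[2] - v0[2] * v1[1])
  coplanar <- abs(sum(v2 * n)) < 1e-10 * sqrt(sum(n^2))
  if (strict) coplanar && u > 0 && v > 0 && w > 0
  else coplanar && u >= 0 && v >= 0 && w >= 0
}

r_angle_deg <- function(u, v) {
  c0 <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(max(c0, -1), 1)) * 180 / pi
}
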