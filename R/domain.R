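# Perfusion domains: axis-aligned boxes, watertight triangulated surfaces,
# and box-mesh intersections (used for partition cells of mesh domains).

#' Create a box perfusion domain
#'
#' An axis-aligned parallelepiped given by two opposite corners, in cm.
#'
#' @param lo,hi numeric length-3: minimum and maximum corners (cm).
#' @param seed integer seed attached to the domain's random stream; point
#'   sampling consumes a deterministic stream derived from it.
#' @return an object of class `perfusion_domain`.
#' @export
#' @examples
#' d <- box_domain(c(0, 0, 0), c(4, 1, 1))
#' domain_volume(d)
box_domain <- function(lo, hi, seed = 1L) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  stopifnot(length(lo) == 3, length(hi) == 3, all(is.finite(c(lo, hi))))
  if (any(hi <= lo)) stop("box domain requires hi > lo on every axis")
  structure(list(type = "box", lo = lo, hi = hi,
                 volume = prod(hi - lo), seed = as.integer(seed)),
            class = "perfusion_domain")
}

#' Create a mesh perfusion domain from a watertight triangulated surface
#'
#' The surface must be watertight (every edge shared by exactly two
#' triangles); non-watertight input is rejected at construction because a
#' silent inside/outside misclassification would corrupt the growth process.
#' The volume is computed exactly from the surface by the divergence theorem.
#'
#' @param vertices numeric matrix (n x 3) of vertex coordinates (cm).
#' @param faces integer matrix (m x 3) of 1-based triangle vertex indices.
#' @param seed integer seed for the domain's sampling stream.
#' @return an object of class `perfusion_domain`.
#' @export
mesh_domain <- function(vertices, faces, seed = 1L) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (!mesh_is_watertight(faces))
    stop("mesh is not watertight: every edge must be shared by exactly two triangles")
  vol <- mesh_volume(vertices, faces)
  if (vol <= 0) stop("mesh encloses no volume")
  structure(list(type = "mesh", vertices = vertices, faces = faces,
                 lo = apply(vertices, 2, min), hi = apply(vertices, 2, max),
                 volume = vol, seed = as.integer(seed)),
            class = "perfusion_domain")
}

# Partition cell of a mesh domain: points must lie in the box cell AND in the
# parent mesh.  Volume is a Monte-Carlo estimate (the analytic intersection
# volume is not generally available); it only feeds the d_crit heuristic.
boxmesh_domain <- function(lo, hi, parent, volume, seed = 1L) {
  structure(list(type = "boxmesh", lo = as.numeric(lo), hi = as.numeric(hi),
                 vertices = parent$vertices, faces = parent$faces,
                 volume = volume, seed = as.integer(seed)),
            class = "perfusion_domain")
}

# low-level descriptor handed to compiled code
.domain_to_cpp <- function(domain) {
  switch(domain$type,
    box = list(type = "box", lo = domain$lo, hi = domain$hi),
    mesh = list(type = "mesh", vertices = domain$vertices,
                faces = domain$faces, volume = domain$volume),
    boxmesh = list(type = "boxmesh", lo = domain$lo, hi = domain$hi,
                   vertices = domain$vertices, faces = domain$faces,
                   volume = domain$volume),
    stop("unknown domain type"))
}

#' Domain volume (cm^3)
#'
#' Exact for boxes (product of edge lengths) and for meshes (divergence
#' theorem on the surface); Monte-Carlo estimate for partition cells of mesh
#' domains.
#'
#' @param domain a `perfusion_domain`.
#' @return volume in cm^3.
#' @export
domain_volume <- function(domain) domain$volume

#' Point-membership test
#'
#' Exact for boxes (closed region); ray-crossing parity on the watertight
#' surface for meshes.
#'
#' @param domain a `perfusion_domain`.
#' @param points numeric length-3 vector or (n x 3) matrix (cm).
#' @return logical vector.
#' @export
#' @examples
#' contains(box_domain(c(0,0,0), c(1,1,1)), c(0.5, 0.5, 0.5))
contains <- function(domain, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3, all(is.finite(points)))
  inbox <- points[, 1] >= domain$lo[1] & points[, 1] <= domain$hi[1] &
           points[, 2] >= domain$lo[2] & points[, 2] <= domain$hi[2] &
           points[, 3] >= domain$lo[3] & points[, 3] <= domain$hi[3]
  if (domain$type == "box") return(inbox)
  inmesh <- cpp_mesh_contains(domain$vertices, domain$faces, points)
  inbox & inmesh
}

#' Sample points uniformly inside a domain
#'
#' Rejection sampling from the bounding box (a direct draw for boxes).  The
#' stream is fully determined by `(seed, stream)`, so repeated calls with the
#' same arguments reproduce the same points.
#'
#' @param domain a `perfusion_domain`.
#' @param n number of points.
#' @param seed seed; defaults to the domain's own seed.
#' @param stream sub-stream index (used to give each subdomain an
#'   independent reproducible stream).
#' @return an (n x 3) matrix of points, all passing [contains()].
#' @export
sample_point <- function(domain, n = 1L, seed = domain$seed, stream = 0L) {
  if (domain_volume(domain) <= 0) stop("domain has non-positive volume")
  cpp_sample_points(.domain_to_cpp(domain), as.integer(n),
                    as.double(seed), as.double(stream))
}

#' Partition a domain into axis-aligned cells
#'
#' Splits the domain's bounding box into `counts = (n_x, n_y, n_z)` equal
#' cells and intersects each with the domain.  Point labelling is half-open
#' (`[low, high)` except the last cell per axis, which is closed), so every
#' point maps to exactly one cell and a vessel midpoint cannot belong to two
#' subdomains.
#'
#' @param domain a `perfusion_domain`.
#' @param counts integer length-3, cells per axis (all >= 1).
#' @param mc_volume_n Monte-Carlo sample size per cell used to estimate cell
#'   volumes of mesh domains (box cells are exact).
#' @return an object of class `domain_partition` with elements
#'   `subdomains` (list of `perfusion_domain`), `counts`, `parent`.
#' @export
#' @examples
#' p <- partition_axis_aligned(box_domain(c(0,0,0), c(4,1,1)), c(4, 1, 1))
#' length(p$subdomains)
partition_axis_aligned <- function(domain, counts, mc_volume_n = 20000L) {
  counts <- as.integer(counts)
  stopifnot(length(counts) == 3)
  if (any(counts < 1L)) stop("partition counts must be positive on every axis")
  lo <- domain$lo; hi <- domain$hi
  w <- (hi - lo) / counts
  subs <- vector("list", prod(counts))
  k <- 0L
  for (kz in seq_len(counts[3])) for (ky in seq_len(counts[2]))
    for (kx in seq_len(counts[1])) {
      k <- k + 1L
      clo <- lo + w * (c(kx, ky, kz) - 1)
      chi <- lo + w * c(kx, ky, kz)
      if (domain$type == "box") {
        subs[[k]] <- box_domain(clo, chi, seed = domain$seed)
      } else {
        pts <- cpp_sample_points(list(type = "box", lo = clo, hi = chi),
                                 mc_volume_n, as.double(domain$seed),
                                 as.double(1000L + k))
        frac <- mean(contains(domain, pts))
        subs[[k]] <- boxmesh_domain(clo, chi, domain,
                                    volume = frac * prod(chi - clo),
                                    seed = domain$seed)
      }
    }
  structure(list(parent = domain, counts = counts, subdomains = subs),
            class = "domain_partition")
}

#' Map points to partition cell labels
#'
#' @param partition a `domain_partition`.
#' @param points length-3 vector or (n x 3) matrix.
#' @return integer vector of 1-based subdomain indices; `NA` for points
#'   outside the partitioned region.
#' @export
label_point <- function(partition, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  dom <- partition$parent
  counts <- partition$counts
  w <- (dom$hi - dom$lo) / counts
  idx <- matrix(0L, nrow(points), 3)
  for (a in 1:3) {
    i <- floor((points[, a] - dom$lo[a]) / w[a])
    # last cell per axis is closed on the upper face
    i[points[, a] == dom$hi[a]] <- counts[a] - 1L
    i[i < 0 | i >= counts[a]] <- NA_integer_
    idx[, a] <- as.integer(i)
  }
  lab <- idx[, 1] + counts[1] * (idx[, 2] + counts[2] * idx[, 3]) + 1L
  inside <- contains(dom, points)
  lab[!inside] <- NA_integer_
  lab
}

#' Allometric scaling of inlet boundary data
#'
#' When the perfusion volume changes from a reference `V_ref` to `V`, the
#' inlet flow scales linearly with volume and the root radius with the 3/8
#' power: `Q = Q_ref (V / V_ref)`, `r0 = r_ref (V / V_ref)^{3/8}`.
#'
#' @param V,V_ref perfusion volumes (cm^3).
#' @param Q_ref reference inlet flow (cm^3/s).
#' @param r_ref reference root radius (cm).
#' @return list with elements `Q` and `r0`.
#' @export
#' @examples
#' allometric_inlet_scaling(V = 2, Q_ref = 1, r_ref = 1, V_ref = 1)
allometric_inlet_scaling <- function(V, Q_ref, r_ref, V_ref) {
  stopifnot(V > 0, Q_ref > 0, r_ref > 0, V_ref > 0)
  list(Q = Q_ref * (V / V_ref), r0 = r_ref * (V / V_ref)^(3 / 8))
}

#' @export
print.perfusion_domain <- function(x, ...) {
  cat(sprintf("<perfusion_domain: %s, volume %.6g cm^3, bbox [%s] - [%s]>\n",
              x$type, x$volume,
              paste(signif(x$lo, 6), collapse = ", "),
              paste(signif(x$hi, 6), collapse = ", ")))
  invisible(x)
}

#' @export
print.domain_partition <- function(x, ...) {
  cat(sprintf("<domain_partition: %d x %d x %d = %d cells of a %s domain>\n",
              x$counts[1], x$counts[2], x$counts[3], prod(x$counts),
              x$parent$type))
  invisible(x)
}
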