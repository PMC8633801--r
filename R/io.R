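# Interchange formats: surface meshes (ASCII STL/OBJ/PLY), tree edge tables
# (CSV, lossless at full floating precision), legacy VTK polydata, and
# JSON-lines insertion records.

# ---- surface meshes ---------------------------------------------------------

#' Watertightness check for a triangulated surface
#'
#' @param faces integer (m x 3) matrix of 1-based vertex indices.
#' @return `TRUE` iff every undirected edge is shared by exactly two
#'   triangles.
#' @export
mesh_is_watertight <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Enclosed volume of a watertight surface (divergence theorem)
#'
#' @param vertices numeric (n x 3) matrix.
#' @param faces integer (m x 3) matrix, consistently oriented.
#' @return volume in cm^3 (absolute value of the signed volume).
#' @export
mesh_volume <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  cc <- vertices[faces[, 3], , drop = FALSE]
  det3 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
          a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
          a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  abs(sum(det3)) / 6
}

#' Read a triangulated surface mesh (ASCII STL, OBJ or PLY)
#'
#' The format is taken from the file extension.  Duplicate vertices in STL
#' files are merged exactly (bitwise-equal coordinates), as STL stores one
#' vertex triple per facet.
#'
#' @param path file path ending in `.stl`, `.obj` or `.ply`.
#' @param seed seed for the resulting domain's sampling stream.
#' @return a mesh `perfusion_domain` (construction validates watertightness).
#' @export
read_mesh <- function(path, seed = 1L) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  if (ext == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    V <- do.call(rbind, lapply(strsplit(vl, "[[:space:]]+"), function(x)
      as.numeric(x[2:4])))
    F <- do.call(rbind, lapply(strsplit(fl, "[[:space:]]+"), function(x)
      as.integer(sub("/.*", "", x[2:4]))))
  } else if (ext == "stl") {
    if (!grepl("^\\s*solid", lines[1]))
      stop("only ASCII STL is supported: ", path)
    vl <- grep("vertex", lines, value = TRUE)
    coords <- do.call(rbind, lapply(strsplit(trimws(vl), "[[:space:]]+"),
                                    function(x) as.numeric(x[2:4])))
    if (nrow(coords) %% 3 != 0) stop("malformed STL: ", path)
    key <- apply(coords, 1, function(p) paste(sprintf("%.17g", p),
                                              collapse = " "))
    uk <- !duplicated(key)
    V <- coords[uk, , drop = FALSE]
    F <- matrix(match(key, key[uk]), ncol = 3, byrow = TRUE)
  } else if (ext == "ply") {
    if (!grepl("^ply", lines[1])) stop("malformed PLY: ", path)
    if (!any(grepl("format ascii", lines))) stop("only ASCII PLY is supported")
    nv <- as.integer(sub(".*element vertex ", "",
                         grep("element vertex", lines, value = TRUE)[1]))
    nf <- as.integer(sub(".*element face ", "",
                         grep("element face", lines, value = TRUE)[1]))
    hdr <- grep("end_header", lines)[1]
    vrows <- lines[(hdr + 1):(hdr + nv)]
    frows <- lines[(hdr + nv + 1):(hdr + nv + nf)]
    V <- do.call(rbind, lapply(strsplit(trimws(vrows), "[[:space:]]+"),
                               function(x) as.numeric(x[1:3])))
    F <- do.call(rbind, lapply(strsplit(trimws(frows), "[[:space:]]+"),
                               function(x) {
      if (as.integer(x[1]) != 3L) stop("PLY faces must be triangles")
      as.integer(x[2:4]) + 1L
    }))
  } else {
    stop("unsupported mesh format: ", ext)
  }
  mesh_domain(V, F, seed = seed)
}

# ---- tree CSV ---------------------------------------------------------------

#' Write a tree as a CSV edge table
#'
#' Coordinates and scalars are printed with 17 significant digits so the
#' round trip is lossless at double precision.
#'
#' @param tree a `vascular_tree`.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_tree_csv <- function(tree, path) {
  df <- as.data.frame(tree)
  num <- vapply(df, is.double, TRUE)
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  hdr <- sprintf("# vasctree edge table v1: root=%d gamma=%.17g Q_in=%.17g r0=%.17g next_id=%d",
                 tree$root, tree$gamma, tree$Q_in, tree$r0, tree$next_id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tree from a CSV edge table
#'
#' Accepts both files written by [write_tree_csv()] (whose header comment
#' carries the inlet data) and handcrafted seed networks, for which `Q_in`,
#' `gamma` and `r0` can be supplied.  The topology must be a strict binary
#' tree (every vessel has zero or two children and there is exactly one
#' root); cyclic or malformed parent references are rejected.
#'
#' @param path CSV file with columns `id, parent, xp_x..xp_z, xd_x..xd_z, r`
#'   and optionally `Q, mu, stage`.
#' @param Q_in,gamma,r0 inlet data when the file has no header comment.
#' @return a `vascular_tree`.
#' @export
read_tree_csv <- function(path, Q_in = NULL, gamma = 3, r0 = NULL) {
  first <- readLines(path, n = 1L)
  meta <- NULL
  if (startsWith(first, "#")) {
    kv <- regmatches(first, gregexpr("[a-zA-Z_]+=[-0-9.e+]+", first))[[1]]
    meta <- as.list(as.numeric(sub(".*=", "", kv)))
    names(meta) <- sub("=.*", "", kv)
  }
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("id", "parent", "xp_x", "xp_y", "xp_z", "xd_x", "xd_y", "xd_z", "r")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("malformed tree table (missing columns): ", paste(miss, collapse = ", "))
  n <- nrow(df)
  id <- as.integer(df$id)
  if (anyDuplicated(id)) stop("duplicate vessel ids")
  parent <- as.integer(df$parent)
  pidx <- match(parent, id)
  bad <- which(!is.na(parent) & is.na(pidx))
  if (length(bad))
    stop("row ", bad[1] + 1L, ": parent id ", parent[bad[1]], " not found")
  # children from parent pointers
  c1 <- rep(NA_integer_, n); c2 <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    p <- pidx[i]
    if (is.na(p)) next
    if (is.na(c1[p])) c1[p] <- id[i]
    else if (is.na(c2[p])) c2[p] <- id[i]
    else stop("vessel ", id[p], " has more than two children")
  }
  roots <- which(is.na(parent))
  if (length(roots) != 1) stop("tree must have exactly one root")
  nch <- (!is.na(c1)) + (!is.na(c2))
  if (any(nch == 1))
    stop("vessel ", id[which(nch == 1)[1]],
         " has exactly one child; topology must be strictly binary")
  # cycle check: every vessel must reach the root
  depth <- rep(NA_integer_, n)
  depth[roots] <- 0L
  for (pass in seq_len(n)) {
    upd <- which(is.na(depth) & !is.na(depth[pidx]))
    if (!length(upd)) break
    depth[upd] <- depth[pidx[upd]] + 1L
  }
  if (anyNA(depth)) stop("cyclic or disconnected parent references")
  Q_in <- if (!is.null(meta$Q_in)) meta$Q_in else Q_in
  r0 <- if (!is.null(meta$r0)) meta$r0 else
    if (is.null(r0)) df$r[roots] else r0
  gamma <- if (!is.null(meta$gamma)) meta$gamma else gamma
  if (is.null(Q_in)) stop("Q_in must be given for headerless tree tables")
  tr <- new_vascular_tree(list(
    id = id, parent = parent, c1 = c1, c2 = c2,
    xp = cbind(df$xp_x, df$xp_y, df$xp_z),
    xd = cbind(df$xd_x, df$xd_y, df$xd_z),
    r = as.numeric(df$r), beta = rep(1, n),
    Q = if ("Q" %in% names(df)) as.numeric(df$Q) else rep(Q_in, n),
    mu = if ("mu" %in% names(df)) as.numeric(df$mu) else rep(0.036, n),
    qfix = rep(NaN, n),
    nterm = rep(1L, n),
    stage = if ("stage" %in% names(df)) as.character(df$stage)
            else rep("loaded", n),
    allowed = rep(TRUE, n),
    root = id[roots],
    gamma = as.numeric(gamma), Q_in = as.numeric(Q_in), r0 = as.numeric(r0),
    next_id = if (!is.null(meta$next_id)) as.integer(meta$next_id)
              else max(id) + 1L))
  tr$nterm <- .recount_nterm(tr)
  validate_tree(tr)
  tr
}

# ---- VTK polydata -----------------------------------------------------------

#' Write a tree as legacy ASCII VTK polydata
#'
#' One polyline cell per vessel (two points), with cell arrays `radius`,
#' `flow`, `pressure` (distal, mmHg), `generation`, `strahler`, and `stage`
#' (integer code; the legend is embedded in the header comment).  Readable by
#' standard VTK viewers.
#'
#' @param tree a `vascular_tree`.
#' @param path output `.vtk` file.
#' @param solution optional [solve_pressures()] result (computed if missing).
#' @return `path` invisibly.
#' @export
write_vtk <- function(tree, path, solution = solve_pressures(tree)) {
  n <- n_segments(tree)
  if (n == 0) stop("empty tree")
  con <- file(path, "w")
  on.exit(close(con))
  levels <- unique(tree$stage)
  writeLines(c("# vtk DataFile Version 3.0",
               paste("vasctree network; stage codes:",
                     paste(sprintf("%d=%s", seq_along(levels), levels),
                           collapse = " ")),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", 2L * n)), con)
  # interleave: point 2i-1 = proximal, 2i = distal of vessel i
  coords <- character(2L * n)
  coords[seq(1, 2 * n, 2)] <- sprintf("%.17g %.17g %.17g",
                                      tree$xp[, 1], tree$xp[, 2], tree$xp[, 3])
  coords[seq(2, 2 * n, 2)] <- sprintf("%.17g %.17g %.17g",
                                      tree$xd[, 1], tree$xd[, 2], tree$xd[, 3])
  writeLines(coords, con)
  writeLines(sprintf("LINES %d %d", n, 3L * n), con)
  writeLines(sprintf("2 %d %d", seq(0, 2 * n - 2, 2), seq(1, 2 * n - 1, 2)),
             con)
  writeLines(sprintf("CELL_DATA %d", n), con)
  warr <- function(name, x, type = "double") {
    writeLines(c(sprintf("SCALARS %s %s 1", name, type),
                 "LOOKUP_TABLE default"), con)
    writeLines(if (type == "double") sprintf("%.17g", x)
               else sprintf("%d", x), con)
  }
  warr("radius", tree$r)
  warr("flow", tree$Q)
  warr("pressure", solution$p_dist[match(tree$id, solution$id)])
  warr("generation", generation_of(tree), "int")
  warr("strahler", strahler_orders(tree), "int")
  warr("stage", match(tree$stage, levels), "int")
  invisible(path)
}

# ---- insertion records (JSON lines) ----------------------------------------

#' Write insertion records as JSON lines
#'
#' One record per line with full-precision coordinates, so that replaying
#' from file resolves the same coordinate keys as replaying in memory.
#'
#' @param records a record data.frame from [grow_subdomain()].
#' @param path output `.jsonl` file.
#' @return `path` invisibly.
#' @export
write_records_jsonl <- function(records, path) {
  fmt <- function(...) sprintf("[%s]", paste(sprintf("%.17g", c(...)),
                                             collapse = ","))
  lines <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    sprintf('{"subdomain":%d,"seq":%d,"x_new":%s,"x_bif":%s,"p_xp":%s,"p_xd":%s}',
            as.integer(r$subdomain), as.integer(r$seq),
            fmt(r$xn_x, r$xn_y, r$xn_z), fmt(r$xb_x, r$xb_y, r$xb_z),
            fmt(r$pp_x, r$pp_y, r$pp_z), fmt(r$pd_x, r$pd_y, r$pd_z))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read insertion records from JSON lines
#'
#' @param path a `.jsonl` file written by [write_records_jsonl()].
#' @return a record data.frame.
#' @export
read_records_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- lapply(lines, jsonlite::fromJSON)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(xn_x = r$x_new[1], xn_y = r$x_new[2], xn_z = r$x_new[3],
               xb_x = r$x_bif[1], xb_y = r$x_bif[2], xb_z = r$x_bif[3],
               pp_x = r$p_xp[1], pp_y = r$p_xp[2], pp_z = r$p_xp[3],
               pd_x = r$p_xd[1], pd_y = r$p_xd[2], pd_z = r$p_xd[3],
               seq = r$seq, subdomain = r$subdomain)
  }))
}

# ---- run configuration ------------------------------------------------------

#' Read a run configuration (JSON)
#'
#' Schema: `domain` (`{type: "box", lo, hi}` or `{type: "mesh", file}`),
#' optional `partition` (`{counts: [nx, ny, nz]}`), `inlet`
#' (`{x_prox, x_dist, r0, Q_in}`), `stages` (list of [stage_config()]
#' fields, nested `cost` and `viscosity` blocks allowed), `seed`.  Unknown
#' top-level keys are rejected so typos fail loudly.
#'
#' @param path JSON file.
#' @return list with `domain`, `partition` (or `NULL`), `inlet`, `stages`
#'   (list of `stage_config`), `seed`, and the raw parsed config as
#'   `resolved`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  known <- c("domain", "partition", "inlet", "stages", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L
  dom <- if (identical(cfg$domain$type, "mesh")) {
    read_mesh(cfg$domain$file, seed = seed)
  } else {
    box_domain(cfg$domain$lo, cfg$domain$hi, seed = seed)
  }
  part <- if (!is.null(cfg$partition))
    partition_axis_aligned(dom, cfg$partition$counts) else NULL
  stages <- NULL
  if (!is.null(cfg$stages)) {
    stages <- lapply(cfg$stages, function(s) {
      s <- Filter(Negate(is.null), s)
      cost <- if (!is.null(s$cost)) do.call(cost_functional, as.list(s$cost))
              else cost_functional()
      visc <- if (!is.null(s$viscosity))
        do.call(viscosity_model, as.list(s$viscosity)) else viscosity_model()
      args <- s[setdiff(names(s), c("cost", "viscosity"))]
      do.call(stage_config, c(args, list(cost = cost, viscosity = visc)))
    })
  }
  list(domain = dom, partition = part, inlet = cfg$inlet, stages = stages,
       seed = seed, resolved = cfg)
}
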