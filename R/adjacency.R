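## Areal maps and the CAR neighbourhood structure.
##
## An `area_map` holds ordered area identifiers and one planar polygon per
## area; an `adjacency_matrix` holds the symmetric rook/queen contiguity
## graph in both list form and the GeoBUGS triplet encoding
## (num / adj / sumNumNeigh).  Indices are 1-based throughout, matching both
## R convention and the GeoBUGS file layout.

#' Construct an areal map
#'
#' @param area_id character vector of unique area identifiers.
#' @param polygons list of two-column numeric matrices (x, y vertex
#'   coordinates, open or closed rings), one per area.
#' @return An object of class `area_map`.
#' @export
area_map <- function(area_id, polygons) {
  area_id <- as.character(area_id)
  if (anyDuplicated(area_id)) stop("area_id values must be unique")
  if (length(area_id) != length(polygons))
    stop("area_id and polygons lengths differ")
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2 || nrow(p) < 3) stop("each polygon needs >= 3 (x, y) vertices")
    # drop an explicit closing vertex; rings are treated as implicitly closed
    if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    unname(p)
  })
  centroids <- t(vapply(polygons, polygon_centroid, numeric(2)))
  structure(list(area_id = area_id, polygons = polygons, centroids = centroids),
            class = "area_map")
}

#' @export
print.area_map <- function(x, ...) {
  cat("area_map:", length(x$area_id), "areas\n")
  invisible(x)
}

polygon_area_signed <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  j <- c(2:nrow(p), 1)
  sum(x * y[j] - x[j] * y) / 2
}

polygon_centroid <- function(p) {
  a <- polygon_area_signed(p)
  if (abs(a) < 1e-300) return(colMeans(p))
  x <- p[, 1]; y <- p[, 2]
  j <- c(2:nrow(p), 1)
  cr <- x * y[j] - x[j] * y
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

#' Construct / validate an adjacency matrix object
#'
#' @param neighbours list of integer vectors; `neighbours[[i]]` are the
#'   1-based indices of the neighbours of area `i`.
#' @param area_id optional character ids carried along for reporting.
#' @param require_connected error if the contiguity graph is disconnected
#'   (the intrinsic CAR prior is improper per component).
#' @return Object of class `adjacency_matrix` with fields `n`, `neighbours`,
#'   `num`, `adj`, `sumNumNeigh`.
#' @export
adjacency_matrix <- function(neighbours, area_id = NULL, require_connected = TRUE) {
  n <- length(neighbours)
  neighbours <- lapply(neighbours, function(v) sort(unique(as.integer(v))))
  ids <- if (is.null(area_id)) as.character(seq_len(n)) else as.character(area_id)
  for (i in seq_len(n)) {
    v <- neighbours[[i]]
    if (length(v) == 0L)
      stop("area ", ids[i], " has no neighbours (island); ICAR is undefined for islands")
    if (any(v < 1L | v > n)) stop("neighbour index out of range for area ", ids[i])
    if (i %in% v) stop("area ", ids[i], " lists itself as a neighbour")
  }
  for (i in seq_len(n)) for (j in neighbours[[i]])
    if (!(i %in% neighbours[[j]]))
      stop("asymmetric adjacency: ", ids[i], " lists ", ids[j],
           " but not vice versa")
  if (require_connected) {
    comp <- graph_components(neighbours)
    if (max(comp) > 1L)
      stop("contiguity graph is disconnected (", max(comp), " components); ",
           "component sizes: ", paste(tabulate(comp), collapse = ", "))
  }
  num <- vapply(neighbours, length, integer(1))
  structure(list(n = n, area_id = ids, neighbours = neighbours,
                 num = num, adj = unlist(neighbours, use.names = FALSE),
                 sumNumNeigh = sum(num)),
            class = "adjacency_matrix")
}

#' @export
print.adjacency_matrix <- function(x, ...) {
  cat("adjacency_matrix:", x$n, "areas,", x$sumNumNeigh / 2, "edges\n")
  invisible(x)
}

# connected-component labels by breadth-first search
graph_components <- function(neighbours) {
  n <- length(neighbours)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      for (j in neighbours[[i]]) if (comp[j] == 0L) { comp[j] <- k; queue <- c(queue, j) }
    }
  }
  comp
}

## ---- contiguity detection -------------------------------------------------

point_segment_dist <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  L2 <- pmax(dx * dx + dy * dy, 1e-300)
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / L2))
  sqrt((ax + t * dx - px)^2 + (ay + t * dy - py)^2)
}

# length of the collinear overlap of segments (a1,a2) and (b1,b2); 0 if not
# collinear within tol
segment_overlap_length <- function(a1, a2, b1, b2, tol) {
  d <- a2 - a1
  L <- sqrt(sum(d^2))
  if (L < tol) return(0)
  u <- d / L
  # both endpoints of b must lie on the (infinite) line through a within tol
  perp <- function(p) abs((p[1] - a1[1]) * (-u[2]) + (p[2] - a1[2]) * u[1])
  if (perp(b1) > tol || perp(b2) > tol) return(0)
  proj <- function(p) (p[1] - a1[1]) * u[1] + (p[2] - a1[2]) * u[2]
  i1 <- sort(c(0, L))
  i2 <- sort(c(proj(b1), proj(b2)))
  max(0, min(i1[2], i2[2]) - max(i1[1], i2[1]))
}

polygon_edges <- function(p) {
  j <- c(2:nrow(p), 1)
  cbind(p, p[j, , drop = FALSE])  # ax ay bx by per row
}

# do polygons pa, pb touch?  rule "rook": share a positive-length collinear
# segment; "queen": additionally a single shared point suffices.
polygons_touch <- function(pa, pb, rule, tol) {
  ea <- polygon_edges(pa); eb <- polygon_edges(pb)
  for (i in seq_len(nrow(ea))) {
    for (j in seq_len(nrow(eb))) {
      len <- segment_overlap_length(ea[i, 1:2], ea[i, 3:4], eb[j, 1:2], eb[j, 3:4],
                                    tol)
      if (len > tol) return(TRUE)
    }
  }
  if (rule == "queen") {
    for (i in seq_len(nrow(pa))) {
      d <- point_segment_dist(pa[i, 1], pa[i, 2], eb[, 1], eb[, 2], eb[, 3], eb[, 4])
      if (any(d <= tol)) return(TRUE)
    }
    for (j in seq_len(nrow(pb))) {
      d <- point_segment_dist(pb[j, 1], pb[j, 2], ea[, 1], ea[, 2], ea[, 3], ea[, 4])
      if (any(d <= tol)) return(TRUE)
    }
  }
  FALSE
}

#' Build the contiguity adjacency matrix of an areal map
#'
#' Two areas are neighbours iff their boundaries share at least one point
#' (`queen`, the GeoBUGS Adjacency Tool behaviour and the default) or a
#' positive-length boundary segment (`rook`).
#'
#' @param map an [area_map].
#' @param rule `"queen"` or `"rook"`.
#' @param snap geometric tolerance for shared-boundary detection.
#' @return An [adjacency_matrix]; errors if the graph is disconnected.
#' @export
build_adjacency <- function(map, rule = c("queen", "rook"), snap = 1e-9) {
  rule <- match.arg(rule)
  stopifnot(inherits(map, "area_map"))
  n <- length(map$polygons)
  bb <- t(vapply(map$polygons,
                 function(p) c(min(p[, 1]), max(p[, 1]), min(p[, 2]), max(p[, 2])),
                 numeric(4)))
  neighbours <- vector("list", n)
  for (i in seq_len(n)) neighbours[[i]] <- integer(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # bounding-box prefilter with tolerance
      if (bb[i, 1] > bb[j, 2] + snap || bb[j, 1] > bb[i, 2] + snap ||
          bb[i, 3] > bb[j, 4] + snap || bb[j, 3] > bb[i, 4] + snap) next
      if (polygons_touch(map$polygons[[i]], map$polygons[[j]], rule, snap)) {
        neighbours[[i]] <- c(neighbours[[i]], j)
        neighbours[[j]] <- c(neighbours[[j]], i)
      }
    }
  }
  adjacency_matrix(neighbours, area_id = map$area_id)
}

## ---- GeoBUGS adjacency file dialect ---------------------------------------

#' Write an adjacency structure as a GeoBUGS-style list file
#'
#' Layout:
#' \preformatted{list(
#' num = c(...),
#' adj = c(
#' ...one line of neighbours per area...
#' ),
#' sumNumNeigh = N
#' )}
#' Indices are 1-based.  The file round-trips through
#' [read_geobugs_adjacency()].
#'
#' @param adj an [adjacency_matrix].
#' @param path output file path.
#' @export
write_geobugs_adjacency <- function(adj, path) {
  stopifnot(inherits(adj, "adjacency_matrix"))
  lines <- c(
    "list(",
    paste0("num = c(", paste(adj$num, collapse = ", "), "),"),
    "adj = c(",
    paste0(vapply(adj$neighbours, function(v) paste(v, collapse = ", "),
                  character(1)),
           c(rep(",", adj$n - 1), "")),
    "),",
    paste0("sumNumNeigh = ", adj$sumNumNeigh),
    ")")
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("cannot write adjacency file '", path,
                                          "': ", conditionMessage(e)))
  invisible(path)
}

extract_numeric_field <- function(txt, field, path) {
  m <- regmatches(txt, regexpr(paste0(field, "\\s*=\\s*c\\(([^)]*)\\)"), txt))
  if (length(m) == 0)
    stop("parse error in '", path, "': field '", field, "' not found")
  body <- sub(paste0("^", field, "\\s*=\\s*c\\("), "", m)
  body <- sub("\\)$", "", body)
  vals <- suppressWarnings(as.numeric(strsplit(body, "[,\\s]+")[[1]]))
  vals <- vals[!is.na(vals)]
  vals
}

#' Read a GeoBUGS-style adjacency list file
#'
#' Accepts the dialect written by [write_geobugs_adjacency()] (whitespace and
#' line breaks are not significant).  The structure is validated: `adj`
#' length must equal both `sum(num)` and `sumNumNeigh`, and the implied graph
#' must be symmetric with no self-neighbours or islands.
#'
#' @param path file path.
#' @param require_connected passed to [adjacency_matrix()].
#' @return An [adjacency_matrix].
#' @export
read_geobugs_adjacency <- function(path, require_connected = TRUE) {
  if (!file.exists(path)) stop("adjacency file '", path, "' does not exist")
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  num <- as.integer(extract_numeric_field(txt, "num", path))
  adjv <- as.integer(extract_numeric_field(txt, "adj", path))
  m <- regmatches(txt, regexpr("sumNumNeigh\\s*=\\s*([0-9]+)", txt))
  if (length(m) == 0) stop("parse error in '", path, "': sumNumNeigh not found")
  snn <- as.integer(sub("sumNumNeigh\\s*=\\s*", "", m))
  if (length(adjv) != snn)
    stop("parse error in '", path, "': adj has ", length(adjv),
         " entries but sumNumNeigh = ", snn)
  if (sum(num) != snn)
    stop("parse error in '", path, "': sum(num) = ", sum(num),
         " but sumNumNeigh = ", snn)
  ends <- cumsum(num)
  starts <- ends - num + 1L
  neighbours <- lapply(seq_along(num), function(i)
    if (num[i] == 0L) integer(0) else adjv[starts[i]:ends[i]])
  adjacency_matrix(neighbours, require_connected = require_connected)
}

## ---- GeoJSON areal map I/O ------------------------------------------------

#' Read an areal map from a GeoJSON FeatureCollection
#'
#' Only `Polygon` (outer ring) and single-polygon `MultiPolygon` geometries
#' are supported; the area identifier is taken from a feature property.
#'
#' @param path GeoJSON file.
#' @param id_property name of the property holding the area id.
#' @return An [area_map].
#' @export
read_geojson_areas <- function(path, id_property = "area_id") {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(g$type) || g$type != "FeatureCollection")
    stop("'", path, "' is not a GeoJSON FeatureCollection")
  ids <- character(0); polys <- list()
  for (f in g$features) {
    id <- f$properties[[id_property]]
    if (is.null(id))
      stop("feature without property '", id_property, "' in '", path, "'")
    geom <- f$geometry
    ring <- switch(geom$type,
                   Polygon = geom$coordinates[[1]],
                   MultiPolygon = {
                     if (length(geom$coordinates) != 1)
                       stop("multi-part MultiPolygon not supported (area ", id, ")")
                     geom$coordinates[[1]][[1]]
                   },
                   stop("unsupported geometry type '", geom$type, "'"))
    coords <- do.call(rbind, lapply(ring, function(xy) c(xy[[1]], xy[[2]])))
    ids <- c(ids, as.character(id))
    polys[[length(polys) + 1L]] <- coords
  }
  area_map(ids, polys)
}

#' Write an areal map (with optional per-area properties) as GeoJSON
#'
#' @param map an [area_map].
#' @param path output path.
#' @param properties optional data.frame of per-area properties (row order =
#'   area order); an `area_id` column is added automatically.
#' @export
write_geojson_areas <- function(map, path, properties = NULL) {
  stopifnot(inherits(map, "area_map"))
  n <- length(map$area_id)
  if (!is.null(properties) && nrow(properties) != n)
    stop("properties must have one row per area")
  features <- lapply(seq_len(n), function(i) {
    p <- map$polygons[[i]]
    ring <- lapply(seq_len(nrow(p)), function(r) c(p[r, 1], p[r, 2]))
    ring[[length(ring) + 1L]] <- ring[[1]]  # close the ring
    props <- list(area_id = map$area_id[i])
    if (!is.null(properties))
      for (nm in setdiff(names(properties), "area_id"))
        props[[nm]] <- properties[[nm]][i]
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
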