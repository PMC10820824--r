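#' Delaunay triangulation of ommatidium centroids
#'
#' Builds the ommatidial lattice from a table of centroid coordinates:
#' the Delaunay triangulation (dual of the hexagonal lattice, so a
#' regular ommatidium acquires its six closest neighbors), the
#' neighbor map from shared triangulation edges, and the convex-hull
#' boundary mask.  Boundary ommatidia are never analyzed for disorder
#' themselves (some of their neighbors are outside the image) but do
#' contribute distances to interior ommatidia.
#'
#' Coordinates follow the image convention (origin top-left, x
#' rightward, y downward, units of pixels); the metric is unaffected by
#' the axis orientation.
#'
#' @param centroids data frame with numeric columns `x` and `y` (and
#'   optionally `id`), one row per ommatidium; at least three
#'   non-collinear points, no duplicates.
#' @return An object of class `eye_lattice`: list with `points` (n x 2
#'   matrix), `edges` (data frame `i`, `j`, `length`, each undirected
#'   edge once), `neighbors` (list of integer vectors), `hull`
#'   (indices of convex-hull points), `triangles` (list of index
#'   triples) and `n`.
#' @export
triangulate <- function(centroids) {
  pts <- as.matrix(centroids[, c("x", "y")])
  storage.mode(pts) <- "double"
  if (nrow(pts) < 3L)
    stop("need at least 3 points to triangulate", call. = FALSE)
  if (anyDuplicated(pts))
    stop("duplicate centroid coordinates", call. = FALSE)
  ctr <- sweep(pts, 2L, colMeans(pts))
  if (min(svd(ctr)$d) < 1e-9 * max(svd(ctr)$d, 1e-300))
    stop("all centroids are collinear; triangulation undefined",
         call. = FALSE)
  dd <- deldir::deldir(pts[, 1L], pts[, 2L], suppressMsge = TRUE)
  es <- dd$delsgs
  i <- pmin(es$ind1, es$ind2)
  j <- pmax(es$ind1, es$ind2)
  keep <- !duplicated(cbind(i, j))
  i <- i[keep]; j <- j[keep]
  len <- sqrt((pts[i, 1L] - pts[j, 1L])^2 + (pts[i, 2L] - pts[j, 2L])^2)
  neighbors <- vector("list", nrow(pts))
  for (k in seq_along(i)) {
    neighbors[[i[k]]] <- c(neighbors[[i[k]]], j[k])
    neighbors[[j[k]]] <- c(neighbors[[j[k]]], i[k])
  }
  tl <- deldir::triang.list(dd)
  triangles <- lapply(tl, function(tr) tr$ptNum)
  structure(list(points = pts, edges = data.frame(i = i, j = j,
                                                  length = len),
                 neighbors = neighbors,
                 hull = as.integer(chull(pts)),
                 triangles = triangles, n = nrow(pts)),
            class = "eye_lattice")
}

#' @export
print.eye_lattice <- function(x, ...) {
  cat("eye_lattice:", x$n, "centroids,", nrow(x$edges), "edges,",
      length(x$hull), "hull points\n")
  invisible(x)
}

#' Restrict analysis to the low-curvature central region
#'
#' Selects the ommatidia entering the disorder statistics: points
#' within a fixed distance of the eye center (estimated as the center
#' of mass of all segmented centroids, where projection distortion
#' from eye curvature is minimal) and not on the convex-hull boundary.
#' Excluded ommatidia still contribute neighbor distances.
#'
#' @param lattice an `eye_lattice` built on the full centroid set.
#' @param radius analysis radius in pixels (default 200 px).
#' @return Integer vector of analyzed point indices (possibly empty,
#'   with a warning).
#' @export
restrict_region <- function(lattice, radius = 200) {
  pts <- lattice$points
  center <- colMeans(pts)
  d <- sqrt((pts[, 1L] - center[1L])^2 + (pts[, 2L] - center[2L])^2)
  keep <- setdiff(which(d <= radius), lattice$hull)
  if (length(keep) == 0L)
    warning("empty analysis set: no non-boundary centroid within ",
            radius, " px of the eye center", call. = FALSE)
  keep
}

#' Per-ommatidium lattice disorder metric
#'
#' For each analyzed ommatidium `i`, finds the largest (`X_max`) and
#' smallest (`X_min`) distance connecting it to its triangulation
#' neighbors and computes the dimensionless local disorder
#' \deqn{D_i = (X_{max,i} - X_{min,i}) / \langle X \rangle,}
#' where \eqn{\langle X \rangle} is the mean neighbor distance over
#' all triangulation edges touching the analyzed region (each
#' undirected edge counted once).  A perfectly regular lattice yields
#' `D = 0` everywhere; the metric is invariant under translation,
#' rotation and uniform scaling.
#'
#' @param lattice an `eye_lattice`; its `edges$length` column supplies
#'   the neighbor distances (possibly perturbed, see
#'   [perturb_distances()]).
#' @param analysis integer indices of analyzed points; defaults to
#'   [restrict_region()] with its default radius.
#' @return A data frame (class `disorder_record`) with one row per
#'   analyzed ommatidium: `id`, `x`, `y`, `n_neighbors`, `X_min`,
#'   `X_max`, `D`; attribute `mean_distance` holds
#'   \eqn{\langle X \rangle}.  Points with fewer than two neighbors
#'   are excluded with a message.
#' @export
disorder_metric <- function(lattice, analysis = restrict_region(lattice)) {
  if (length(analysis) == 0L)
    stop("empty analysis set; nothing to measure", call. = FALSE)
  ed <- lattice$edges
  touching <- ed$i %in% analysis | ed$j %in% analysis
  mean_distance <- mean(ed$length[touching])
  # edge rows incident to each point
  inc <- split(rep(seq_len(nrow(ed)), 2L), c(ed$i, ed$j))
  rows <- lapply(analysis, function(pt) {
    eids <- inc[[as.character(pt)]]
    if (is.null(eids) || length(eids) < 2L) return(NULL)
    len <- ed$length[eids]
    data.frame(id = pt, x = lattice$points[pt, 1L],
               y = lattice$points[pt, 2L], n_neighbors = length(eids),
               X_min = min(len), X_max = max(len),
               D = (max(len) - min(len)) / mean_distance)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L)
    message(dropped, " point(s) with fewer than 2 neighbors excluded")
  out <- do.call(rbind, rows)
  attr(out, "mean_distance") <- mean_distance
  class(out) <- c("disorder_record", "data.frame")
  out
}

#' Multiplicative perturbation of neighbor distances
#'
#' Emulates distance-level measurement error: each undirected
#' triangulation edge length is multiplied by an independent
#' `1 + U(-half_width, +half_width)` factor.  With `half_width = 0.1`
#' (10% measurement error) the expected per-ommatidium range of six
#' independent distances is `0.2 * 5/7` of the spacing, i.e. a mean
#' disorder near 0.14.
#'
#' @param lattice an `eye_lattice`.
#' @param half_width half-width of the uniform relative error
#'   (`0 <= half_width < 1` keeps distances positive).
#' @param seed integer RNG seed.
#' @return A copy of the lattice with perturbed `edges$length`.
#' @export
perturb_distances <- function(lattice, half_width, seed = 1L) {
  if (half_width < 0) stop("half_width must be >= 0", call. = FALSE)
  set.seed(seed)
  f <- 1 + runif(nrow(lattice$edges), -half_width, half_width)
  lattice$edges$length <- lattice$edges$length * f
  attr(lattice, "distance_noise") <- half_width
  lattice
}

#' Global lattice features and their dispersion
#'
#' The three classical regularity features of the triangulated
#' lattice: triangle edge lengths, triangle areas and the angles at
#' triangle vertices.  Each feature is uniform on a perfectly regular
#' lattice; dispersion is summarized by the coefficient of variation
#' and the Fano factor.
#'
#' @param lattice an `eye_lattice`.
#' @return List with `features` (named list of numeric vectors:
#'   `edge_length` in px, `triangle_area` in px^2, `vertex_angle` in
#'   degrees) and `dispersion` (data frame: feature, cv, fano).
#' @export
lattice_features <- function(lattice) {
  pts <- lattice$points
  edge_length <- lattice$edges$length
  areas <- vapply(lattice$triangles, function(tr) {
    a <- pts[tr[1L], ]; b <- pts[tr[2L], ]; c <- pts[tr[3L], ]
    abs((b[1L] - a[1L]) * (c[2L] - a[2L]) -
        (c[1L] - a[1L]) * (b[2L] - a[2L])) / 2
  }, numeric(1))
  angles <- unlist(lapply(lattice$triangles, function(tr) {
    p <- pts[tr, , drop = FALSE]
    sapply(1:3, function(v) {
      u <- p[setdiff(1:3, v)[1L], ] - p[v, ]
      w <- p[setdiff(1:3, v)[2L], ] - p[v, ]
      acos(pmin(1, pmax(-1, sum(u * w) /
        (sqrt(sum(u^2)) * sqrt(sum(w^2)))))) * 180 / pi
    })
  }))
  disp <- function(x) c(cv = sd(x) / mean(x), fano = var(x) / mean(x))
  dispersion <- data.frame(
    feature = c("edge_length", "triangle_area", "vertex_angle"),
    rbind(disp(edge_length), disp(areas), disp(angles)))
  list(features = list(edge_length = edge_length, triangle_area = areas,
                       vertex_angle = angles),
       dispersion = dispersion)
}

#' Bootstrap distribution of the mean disorder
#'
#' Resamples the per-ommatidium `D` values with replacement at the
#' original sample size (10,000 draws by default), records the mean of
#' each bootstrap sample, and fits a Gaussian by the method of moments.
#'
#' @param values numeric vector of per-ommatidium `D` measurements (at
#'   least 2).
#' @param n_boot number of bootstrap draws.
#' @param seed integer RNG seed.
#' @return An object of class `disorder_distribution`: list with
#'   `boot_means`, `mean`, `sd` (the Gaussian fit), `sample_mean`,
#'   `n`, `n_boot`, `seed`, `offset` (centering shift applied so far,
#'   0 initially).
#' @export
bootstrap_mean <- function(values, n_boot = 10000L, seed = 1L) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need at least 2 values to bootstrap", call. = FALSE)
  set.seed(seed)
  bm <- vapply(seq_len(n_boot), function(b)
    mean(values[sample.int(n, n, replace = TRUE)]), numeric(1))
  structure(list(boot_means = bm, mean = mean(bm), sd = sd(bm),
                 sample_mean = mean(values), n = n, n_boot = n_boot,
                 seed = seed, offset = 0),
            class = "disorder_distribution")
}

#' Center bootstrap distributions for cross-genotype comparison
#'
#' Subtracts the reference distribution's mean from both
#' distributions, so the reference is centered at zero and the other
#' distribution keeps exactly its difference of means.  Applying the
#' operation twice is equivalent to applying it once.
#'
#' @param reference,other `disorder_distribution` objects from the
#'   same pipeline settings.
#' @return List with shifted `reference` and `other`.
#' @export
center_for_comparison <- function(reference, other) {
  shift <- reference$mean
  shift_one <- function(d) {
    d$boot_means <- d$boot_means - shift
    d$mean <- d$mean - shift
    d$sample_mean <- d$sample_mean - shift
    d$offset <- d$offset + shift
    d
  }
  list(reference = shift_one(reference), other = shift_one(other))
}
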