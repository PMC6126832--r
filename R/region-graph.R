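#' District contiguity graph
#'
#' Represents the neighbourhood structure used by the structured spatial
#' effect: regions are neighbours if they share a common border.  The
#' implied Gaussian Markov random field precision structure `K` has
#' `K[i,i] = degree(i)` and `K[i,j] = -1` for neighbours; its row sums
#' are zero and its rank is `n_regions - n_components`.  Adjacency is
#' unweighted and binary.  Degree-zero regions (islands) are allowed;
#' their structured effect is pinned at zero by the sampler and flagged
#' here.
#'
#' @param regions Vector of unique region identifiers.  Regions with no
#'   hospitals are allowed (and receive structured effects informed by
#'   their neighbours).
#' @param edges Two-column data frame or matrix of neighbouring region
#'   pairs; symmetrized and deduplicated, self-edges rejected.
#' @param coarse_map Optional named vector mapping each region to a
#'   coarse (NUTS2-style) region, for mixed-level spatial models.
#' @return An object of class `region_graph`.
#' @export
region_graph <- function(regions, edges, coarse_map = NULL) {
  regions <- as.character(regions)
  if (anyDuplicated(regions)) abort("Region ids must be unique.")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) abort("`edges` needs two columns.")
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  dangling <- setdiff(c(a, b), regions)
  if (length(dangling)) {
    abort(paste0("Edge list references unknown regions: ",
                 paste(head(dangling, 5), collapse = ", ")))
  }
  if (any(a == b)) abort("Self-edges are not allowed.")
  i <- match(a, regions); j <- match(b, regions)
  lo <- pmin(i, j); hi <- pmax(i, j)
  keep <- !duplicated(cbind(lo, hi))
  lo <- lo[keep]; hi <- hi[keep]
  n <- length(regions)
  if (length(lo)) {
    K <- Matrix::sparseMatrix(
      i = c(lo, hi), j = c(hi, lo), x = -1, dims = c(n, n))
    deg <- -Matrix::rowSums(K)
    Matrix::diag(K) <- deg
  } else {
    K <- Matrix::Diagonal(n, 0)
    deg <- rep(0, n)
  }
  comp <- graph_components(n, lo, hi)
  if (!is.null(coarse_map)) {
    coarse_map <- setNames(as.character(coarse_map), names(coarse_map))
    miss <- setdiff(regions, names(coarse_map))
    if (length(miss)) {
      abort(paste0("coarse_map missing regions: ",
                   paste(head(miss, 5), collapse = ", ")))
    }
    coarse_map <- coarse_map[regions]
  }
  structure(
    list(regions = regions,
         edges = tibble::tibble(from = regions[lo], to = regions[hi]),
         K = K, degree = unname(deg), component = comp,
         coarse_map = coarse_map),
    class = "region_graph")
}

# connected components by breadth-first search over the (deduplicated)
# undirected edge set
graph_components <- function(n, lo, hi) {
  adj <- vector("list", n)
  for (k in seq_along(lo)) {
    adj[[lo[k]]] <- c(adj[[lo[k]]], hi[k])
    adj[[hi[k]]] <- c(adj[[hi[k]]], lo[k])
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' @export
print.region_graph <- function(x, ...) {
  cat(sprintf("<region_graph> %d regions, %d edges, %d component(s)\n",
              length(x$regions), nrow(x$edges), max(x$component)))
  if (any(x$degree == 0)) {
    cat(sprintf("  islands (degree 0): %d\n", sum(x$degree == 0)))
  }
  if (!is.null(x$coarse_map)) {
    cat(sprintf("  coarse regions: %d\n", length(unique(x$coarse_map))))
  }
  invisible(x)
}

#' @rdname region_graph
#' @param x A `region_graph`.
#' @export
precision_matrix <- function(x) x$K

#' Read a contiguity graph from a two-column edge list
#'
#' @param path Delimited text file (comma or tab) whose first two columns
#'   name neighbouring regions; a header line is detected automatically.
#' @param regions Optional full region vector (to include regions without
#'   edges or hospitals); defaults to the ids seen in the file.
#' @param coarse_map Passed to [region_graph()].
#' @return A `region_graph`.
#' @export
build_graph_from_edgelist <- function(path, regions = NULL, coarse_map = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  header <- grepl("[A-Za-z]{2,}", strsplit(first, sep)[[1]][1]) &&
    !grepl("^[0-9.]+$", strsplit(first, sep)[[1]][1])
  df <- utils::read.table(path, header = header, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0) abort("Empty edge list.")
  regions <- regions %||% sort(unique(c(as.character(df[[1]]),
                                        as.character(df[[2]]))))
  region_graph(regions, df[, 1:2], coarse_map = coarse_map)
}

#' Build a contiguity graph from GeoJSON polygons
#'
#' Two regions are neighbours when their polygon boundaries share at
#' least one full edge segment (two consecutive identical vertices), the
#' discrete analogue of a common border of nonzero length.  Intended for
#' simple, topologically clean polygon collections such as exported
#' choropleth geometries; an edge list is the primary input format.
#'
#' @param path GeoJSON `FeatureCollection` of `Polygon`/`MultiPolygon`
#'   features; the region id is taken from the `id` (or `name`) property.
#' @return A `region_graph`.
#' @export
build_graph_from_polygons <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  if (is.null(feats) || !length(feats)) abort("No features in GeoJSON.")
  ids <- character(0)
  segs <- vector("list", length(feats))
  ring_segments <- function(ring) {
    pts <- vapply(ring, function(p) sprintf("%.9g,%.9g", p[[1]], p[[2]]), "")
    n <- length(pts)
    if (n < 2) return(character(0))
    a <- pts[-n]; b <- pts[-1]
    paste(pmin(a, b), pmax(a, b), sep = "|")
  }
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    id <- f$properties$id %||% f$properties$name %||% f$id
    if (is.null(id)) abort(sprintf("Feature %d has no id property.", k))
    ids[k] <- as.character(id)
    geom <- f$geometry
    coords <- if (identical(geom$type, "Polygon")) list(geom$coordinates)
              else geom$coordinates
    segs[[k]] <- unique(unlist(lapply(coords, function(poly) {
      unlist(lapply(poly, ring_segments))
    })))
  }
  if (anyDuplicated(ids)) abort("Duplicate region ids in GeoJSON.")
  n <- length(ids)
  from <- character(0); to <- character(0)
  seg_owner <- data.frame(seg = unlist(segs),
                          id = rep(ids, lengths(segs)),
                          stringsAsFactors = FALSE)
  shared <- split(seg_owner$id, seg_owner$seg)
  for (owners in shared) {
    owners <- unique(owners)
    if (length(owners) >= 2) {
      prs <- utils::combn(owners, 2)
      from <- c(from, prs[1, ]); to <- c(to, prs[2, ])
    }
  }
  pairs <- unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
  region_graph(ids, pairs)
}

#' GMRF quadratic form
#'
#' Evaluates `f' K f`, the sum of squared differences of the effect over
#' all neighbouring region pairs.  It is the (scaled) negative
#' log-density kernel of the intrinsic GMRF prior and is zero exactly
#' when `f` is constant on every connected component.
#'
#' @param f Numeric effect vector, one value per region, in the order of
#'   `graph$regions` (or named by region).
#' @param graph A `region_graph`.
#' @return Non-negative scalar.
#' @export
gmrf_quadform <- function(f, graph) {
  f <- align_region_vector(f, graph)
  as.numeric(f %*% (graph$K %*% f))
}

align_region_vector <- function(f, graph) {
  n <- length(graph$regions)
  if (!is.null(names(f))) {
    miss <- setdiff(graph$regions, names(f))
    if (length(miss)) {
      abort(paste0("Effect vector missing regions: ",
                   paste(head(miss, 5), collapse = ", ")))
    }
    f <- f[graph$regions]
  } else if (length(f) != n) {
    abort(sprintf("Effect vector has length %d, graph has %d regions.",
                  length(f), n))
  }
  unname(as.numeric(f))
}

# subtract the component-wise mean: the sum-to-zero identification
# constraint of the intrinsic GMRF (the frontier intercept / inefficiency
# scale absorbs the level)
center_by_component <- function(f, graph) {
  means <- tapply(f, graph$component, mean)
  f - as.numeric(means[graph$component])
}

#' Draw the structured spatial effect from its Gaussian full conditional
#'
#' Given per-region Gaussian likelihood contributions (precision and
#' linear term, i.e. the log-likelihood in `f` is
#' `-0.5 f' diag(p) f + l' f` up to a constant), draws the full spatial
#' field from the Gaussian with precision `K / tau2 + diag(p)` and then
#' re-centers the draw to satisfy the sum-to-zero constraint on each
#' connected component.  Regions with no data (`p = 0`) receive draws
#' informed only by their neighbours.
#'
#' @param graph A `region_graph`.
#' @param tau2 Positive GMRF variance parameter.
#' @param data_precision Non-negative per-region precision contributions.
#' @param data_linear Per-region linear terms.
#' @param center Apply the sum-to-zero constraint (default `TRUE`).
#' @return A numeric vector of length `length(graph$regions)`.
#' @export
sample_structured_effect <- function(graph, tau2, data_precision,
                                     data_linear, center = TRUE) {
  assert_positive(tau2, "tau2")
  n <- length(graph$regions)
  p <- align_region_vector(data_precision, graph)
  l <- align_region_vector(data_linear, graph)
  if (any(p < 0)) abort("`data_precision` must be non-negative.")
  Q <- graph$K / tau2 + Matrix::Diagonal(n, p)
  ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Q), perm = TRUE,
                                  LDL = FALSE),
                 warning = function(w) NULL, error = function(e) NULL)
  if (is.null(ch)) {
    # singular: data carry no information on some component's level; a
    # tiny ridge pins that level before the constraint re-centers it
    Q2 <- Q + Matrix::Diagonal(n, 1e-8)
    ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Q2), perm = TRUE,
                                    LDL = FALSE),
                   error = function(e) {
                     abort(paste0(
                       "Singular full-conditional precision for the structured effect ",
                       sprintf("(tau2 = %.3g, %d regions with data).",
                               tau2, sum(p > 0))))
                   })
    Q <- Q2
  }
  mu <- as.numeric(Matrix::solve(ch, l, system = "A"))
  z <- rnorm(n)
  # solve L' x = z in the permuted system, then undo the permutation
  Lmat <- Matrix::expand(ch)
  x <- as.numeric(Matrix::crossprod(
    Lmat$P, Matrix::solve(Matrix::t(Lmat$L), z)))
  f <- mu + x
  if (center) f <- center_by_component(f, graph)
  f
}
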