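#' Construct a region-by-year count panel
#'
#' A count panel holds the observed case counts and populations at risk for a
#' set of regions over a run of consecutive calendar years. It is the central
#' data container: standardization, scanning and model fitting all index into
#' its matrices, and the region order fixed here is the canonical order used
#' by adjacency graphs and centroid tables.
#'
#' @param region_ids character vector of unique region labels; their order is
#'   the canonical region order.
#' @param years integer vector of strictly consecutive calendar years.
#' @param observed integer matrix (regions x years) of case counts, >= 0.
#' @param population numeric matrix (regions x years) of populations, > 0.
#' @return An object of class `count_panel` with elements `region_ids`,
#'   `years`, `observed`, `population`.
#' @export
count_panel <- function(region_ids, years, observed, population) {
  region_ids <- as.character(region_ids)
  years <- as.integer(years)
  if (anyDuplicated(region_ids))
    stop("region_ids must be unique")
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("years must be strictly consecutive integers")
  observed <- as.matrix(observed)
  population <- as.matrix(population)
  if (!all(dim(observed) == c(length(region_ids), length(years))))
    stop("observed must be a regions x years matrix")
  if (!all(dim(population) == dim(observed)))
    stop("population must have the same shape as observed")
  if (anyNA(observed) || anyNA(population))
    stop("panel has missing cells")
  if (any(observed < 0) || any(observed != round(observed)))
    stop("observed counts must be non-negative integers")
  if (any(population <= 0))
    stop("all populations must be positive")
  dimnames(observed) <- dimnames(population) <- list(region_ids, years)
  structure(
    list(region_ids = region_ids, years = years,
         observed = observed, population = population),
    class = "count_panel")
}

#' @export
print.count_panel <- function(x, ...) {
  cat(sprintf("count_panel: %d regions x %d years (%d-%d), %d cases\n",
              length(x$region_ids), length(x$years),
              min(x$years), max(x$years), sum(x$observed)))
  invisible(x)
}

#' Read a count panel from a long-format delimited file
#'
#' The file must be in long (tidy) format with one row per region-year cell.
#' Completeness is enforced: every region must appear in every year exactly
#' once, and the panel fails loudly, listing the offending cells, otherwise.
#'
#' @param path path to a delimited text file.
#' @param columns named character vector mapping the panel fields to column
#'   names in the file; defaults to `c(region = "region", year = "year",
#'   observed = "observed", population = "population")`.
#' @param sep field separator, default comma.
#' @return A [count_panel].
#' @export
read_panel <- function(path,
                       columns = c(region = "region", year = "year",
                                   observed = "observed",
                                   population = "population"),
                       sep = ",") {
  need <- c("region", "year", "observed", "population")
  if (!all(need %in% names(columns)))
    stop("columns must map region, year, observed, population")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(columns[need]), names(df))
  if (length(missing_cols))
    stop("file lacks columns: ", paste(missing_cols, collapse = ", "))
  region <- as.character(df[[columns[["region"]]]])
  year <- as.integer(df[[columns[["year"]]]])
  obs <- df[[columns[["observed"]]]]
  pop <- df[[columns[["population"]]]]
  if (any(obs != round(obs)))
    stop("non-integer observed counts in panel file")
  key <- paste(region, year, sep = "/")
  if (anyDuplicated(key))
    stop("duplicate (region, year) rows: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  region_ids <- unique(region)            # first-appearance order
  years <- sort(unique(year))
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("years are not consecutive: ", paste(years, collapse = ", "))
  full <- as.vector(outer(region_ids, years, paste, sep = "/"))
  gaps <- setdiff(full, key)
  if (length(gaps))
    stop("missing region-year cells: ", paste(gaps, collapse = ", "))
  idx <- match(full, key)
  obs_m <- matrix(as.integer(obs[idx]), nrow = length(region_ids),
                  dimnames = list(region_ids, years))
  pop_m <- matrix(as.numeric(pop[idx]), nrow = length(region_ids),
                  dimnames = list(region_ids, years))
  count_panel(region_ids, years, obs_m, pop_m)
}

#' Write a count panel to a long-format CSV
#'
#' Inverse of [read_panel]: rows ordered by year within region, regions in
#' canonical order, so write-then-read round-trips exactly.
#'
#' @param panel a [count_panel].
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  df <- data.frame(
    region = rep(panel$region_ids, each = length(panel$years)),
    year = rep(panel$years, times = length(panel$region_ids)),
    observed = as.integer(t(panel$observed)),
    population = as.vector(t(panel$population)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a region adjacency graph
#'
#' Stores the neighbourhood structure used by the intrinsic CAR prior. The
#' graph is validated as symmetric with no self-loops; isolated regions
#' (islands) are permitted but flagged with a warning, and connectivity of
#' the whole graph is recorded.
#'
#' @param region_ids character vector, same canonical order as the panel.
#' @param neighbors list (one element per region) of integer vectors of
#'   neighbouring region indices.
#' @return An object of class `adjacency_graph` with elements `region_ids`,
#'   `neighbors`, `degree`, `connected`, `islands`.
#' @export
adjacency_graph <- function(region_ids, neighbors) {
  region_ids <- as.character(region_ids)
  n <- length(region_ids)
  if (length(neighbors) != n)
    stop("neighbors must have one entry per region")
  neighbors <- lapply(neighbors, function(v) sort(unique(as.integer(v))))
  for (i in seq_len(n)) {
    if (any(neighbors[[i]] < 1L | neighbors[[i]] > n))
      stop("neighbor index out of range for region ", region_ids[i])
    if (i %in% neighbors[[i]])
      stop("self-loop at region ", region_ids[i])
    for (j in neighbors[[i]])
      if (!(i %in% neighbors[[j]]))
        stop("asymmetric adjacency: ", region_ids[i], " -> ", region_ids[j])
  }
  neighbors <- unname(neighbors)
  degree <- vapply(neighbors, length, integer(1))
  islands <- region_ids[degree == 0L]
  if (length(islands))
    warning("island region(s) with no neighbours: ",
            paste(islands, collapse = ", "))
  # connectivity by breadth-first search from region 1
  seen <- rep(FALSE, n)
  if (n > 0) {
    queue <- 1L; seen[1L] <- TRUE
    while (length(queue)) {
      i <- queue[1L]; queue <- queue[-1L]
      fresh <- setdiff(neighbors[[i]], which(seen))
      seen[fresh] <- TRUE
      queue <- c(queue, fresh)
    }
  }
  structure(
    list(region_ids = region_ids, neighbors = neighbors, degree = degree,
         connected = all(seen), islands = islands),
    class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("adjacency_graph: %d regions, %d edges, %s\n",
              length(x$region_ids), sum(x$degree) / 2,
              if (x$connected) "connected" else "NOT connected"))
  invisible(x)
}

# snap a coordinate pair to a hashable key; tolerance absorbs floating noise
.vertex_keys <- function(coords) {
  paste(round(coords[, 1], 8), round(coords[, 2], 8), sep = "|")
}

# pull every ring vertex out of a GeoJSON Polygon / MultiPolygon geometry
.geometry_vertices <- function(geom) {
  rings <- switch(geom$type,
    Polygon = geom$coordinates,
    MultiPolygon = do.call(c, geom$coordinates),
    stop("unsupported geometry type: ", geom$type))
  pts <- do.call(rbind, lapply(rings, function(r)
    do.call(rbind, lapply(r, function(p) as.numeric(p[1:2])))))
  unique(.vertex_keys(pts))
}

#' Build a queen-contiguity adjacency graph from polygons
#'
#' Two regions are neighbours iff their polygons share at least one boundary
#' point (queen rule: an edge or a single corner both count). Boundary points
#' are matched on polygon vertices after snapping coordinates to 1e-8
#' degrees, which is exact for lattices and for polygon layers whose shared
#' boundaries carry shared vertices.
#'
#' @param path path to a GeoJSON FeatureCollection, one (Multi)Polygon
#'   feature per region.
#' @param region_ids character vector of panel regions (canonical order);
#'   every region must have a feature.
#' @param region_property name of the feature property holding the region
#'   label, default `"region"`.
#' @return An [adjacency_graph].
#' @export
build_adjacency <- function(path, region_ids, region_property = "region") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features))
    stop("not a GeoJSON FeatureCollection")
  labels <- vapply(gj$features, function(f)
    as.character(f$properties[[region_property]]), character(1))
  region_ids <- as.character(region_ids)
  absent <- setdiff(region_ids, labels)
  if (length(absent))
    stop("panel region(s) with no polygon: ", paste(absent, collapse = ", "))
  verts <- lapply(region_ids, function(r) {
    f <- gj$features[[match(r, labels)]]
    .geometry_vertices(f$geometry)
  })
  n <- length(region_ids)
  neighbors <- vector("list", n)
  for (i in seq_len(n)) neighbors[[i]] <- integer(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (length(intersect(verts[[i]], verts[[j]]))) {
      neighbors[[i]] <- c(neighbors[[i]], j)
      neighbors[[j]] <- c(neighbors[[j]], i)
    }
  }
  adjacency_graph(region_ids, neighbors)
}

#' Read an adjacency list from a plain-text file
#'
#' One line per region, `region: neighbour neighbour ...`. The graph is
#' symmetrized: if A lists B but B does not list A, the missing direction is
#' completed and reported via a message.
#'
#' @param path path to the text file.
#' @param region_ids optional canonical region order; defaults to the file's
#'   line order. Neighbour labels not among the regions are an error.
#' @return An [adjacency_graph].
#' @export
read_adjacency_list <- function(path, region_ids = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ":", fixed = TRUE)
  labels <- trimws(vapply(parts, `[`, character(1), 1L))
  nb_labels <- lapply(parts, function(p) {
    rhs <- if (length(p) > 1) p[[2]] else ""
    strsplit(trimws(rhs), "[[:space:]]+")[[1]]
  })
  nb_labels <- lapply(nb_labels, function(v) v[nzchar(v)])
  if (is.null(region_ids)) region_ids <- labels
  region_ids <- as.character(region_ids)
  if (!setequal(labels, region_ids) || anyDuplicated(labels))
    stop("adjacency file regions do not match the panel regions")
  ord <- match(region_ids, labels)
  neighbors <- lapply(nb_labels[ord], function(v) {
    idx <- match(v, region_ids)
    if (anyNA(idx))
      stop("unknown neighbour label(s): ",
           paste(v[is.na(idx)], collapse = ", "))
    idx
  })
  completed <- character(0)
  n <- length(region_ids)
  for (i in seq_len(n)) for (j in neighbors[[i]]) {
    if (!(i %in% neighbors[[j]])) {
      neighbors[[j]] <- c(neighbors[[j]], i)
      completed <- c(completed,
                     paste0(region_ids[j], " -> ", region_ids[i]))
    }
  }
  if (length(completed))
    message("symmetrized adjacency, added: ",
            paste(completed, collapse = "; "))
  adjacency_graph(region_ids, neighbors)
}

#' Region centroid table
#'
#' @param region_ids character vector, canonical order.
#' @param latitude,longitude numeric vectors in decimal degrees.
#' @return An object of class `region_centroids`.
#' @export
region_centroids <- function(region_ids, latitude, longitude) {
  region_ids <- as.character(region_ids)
  if (length(latitude) != length(region_ids) ||
      length(longitude) != length(region_ids))
    stop("one centroid per region required")
  if (any(abs(latitude) > 90) || any(abs(longitude) > 180))
    stop("centroid coordinates out of range")
  structure(
    list(region_ids = region_ids, latitude = as.numeric(latitude),
         longitude = as.numeric(longitude)),
    class = "region_centroids")
}

#' Read region centroids from a CSV with columns region, latitude, longitude
#' @param path path to the CSV file.
#' @param region_ids optional canonical region order to align to.
#' @return A [region_centroids].
#' @export
read_centroids <- function(path, region_ids = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("region", "latitude", "longitude") %in% names(df)))
    stop("centroid file needs columns region, latitude, longitude")
  if (is.null(region_ids)) region_ids <- df$region
  idx <- match(as.character(region_ids), as.character(df$region))
  if (anyNA(idx))
    stop("centroids missing for: ",
         paste(region_ids[is.na(idx)], collapse = ", "))
  region_centroids(region_ids, df$latitude[idx], df$longitude[idx])
}

#' Write a result set as a deterministic delimited table
#'
#' Writes a data frame (or a list of cluster results, which is flattened via
#' [as.data.frame]) as CSV with a fixed header and the input row order, so
#' identical inputs produce byte-identical files. An empty result set yields
#' a header-only file.
#'
#' @param records data frame, or an object with an `as.data.frame` method
#'   (e.g. the cluster list returned by [scan_clusters]).
#' @param path output path.
#' @export
write_results_table <- function(records, path) {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}
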