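#' Georeferenced raster grid
#'
#' A lightweight in-memory raster container used throughout the package: a
#' matrix (single band) or three-dimensional array (rows x cols x bands) of
#' cell values together with an affine georeference (top-left origin, square
#' cells), a CRS tag and an optional set of categorical level labels.
#' Row 1 is the northernmost row; cell centres are at half-cell offsets
#' (pixel-centre convention).
#'
#' @param values numeric matrix or 3-d array of cell values; `NA` is the
#'   in-memory nodata representation.
#' @param res cell size in metres (square cells).
#' @param xmin x coordinate of the left (western) edge of the grid.
#' @param ymax y coordinate of the top (northern) edge of the grid.
#' @param crs free-text CRS tag; the package works in an arbitrary projected
#'   CRS with metre units.
#' @param levels optional character vector of class labels for categorical
#'   rasters; cell values are then integer codes into this vector.
#' @param nodata nodata sentinel used when writing to disk (in memory the
#'   sentinel is always `NA`).
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, res, xmin = 0, ymax = NULL, crs = "local-metric",
                        levels = NULL, nodata = -9999) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  stopifnot(length(dim(values)) == 3L, res > 0)
  if (is.null(ymax)) ymax <- dim(values)[1] * res
  structure(list(values = values, res = res, xmin = xmin, ymax = ymax,
                 crs = crs, levels = levels, nodata = nodata),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("raster_grid: %d x %d cells, %d band(s), %g m resolution\n",
              d[1], d[2], d[3], x$res))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g] (%s)\n",
              x$xmin, x$xmin + d[2] * x$res, x$ymax - d[1] * x$res, x$ymax,
              x$crs))
  if (!is.null(x$levels))
    cat("  categorical levels:", paste(x$levels, collapse = ", "), "\n")
  v <- x$values[, , 1]
  cat(sprintf("  band 1 range: [%g, %g], %d NA cells\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

is_raster_grid <- function(x) inherits(x, "raster_grid")

rg_nrow  <- function(x) dim(x$values)[1]
rg_ncol  <- function(x) dim(x$values)[2]
rg_nband <- function(x) dim(x$values)[3]

#' Band of a raster as a plain matrix
#' @param x a `raster_grid`.
#' @param band band index.
#' @return numeric matrix.
#' @export
rg_band <- function(x, band = 1L) {
  v <- x$values[, , band, drop = FALSE]
  dim(v) <- dim(v)[1:2]
  v
}

#' Cell-centre coordinates
#'
#' @param x a `raster_grid`.
#' @return list with numeric vectors `x` (west to east, per column) and `y`
#'   (north to south, per row) of cell-centre coordinates.
#' @export
rg_centers <- function(x) {
  list(x = x$xmin + (seq_len(rg_ncol(x)) - 0.5) * x$res,
       y = x$ymax - (seq_len(rg_nrow(x)) - 0.5) * x$res)
}

#' Locate points in a raster
#'
#' Maps projected point coordinates to (row, col) indices using the
#' pixel-centre convention; points outside the grid get `NA` indices.
#'
#' @param rast a `raster_grid`.
#' @param x,y point coordinates in the raster CRS.
#' @return data.frame with integer columns `row` and `col`.
#' @export
rg_cell_of <- function(rast, x, y) {
  col <- floor((x - rast$xmin) / rast$res) + 1L
  row <- floor((rast$ymax - y) / rast$res) + 1L
  bad <- col < 1L | col > rg_ncol(rast) | row < 1L | row > rg_nrow(rast)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Extract cell values at point locations
#' @param rast a `raster_grid`.
#' @param x,y point coordinates.
#' @param band band index.
#' @return numeric vector of cell values (`NA` outside the grid or at nodata).
#' @export
rg_extract <- function(rast, x, y, band = 1L) {
  rc <- rg_cell_of(rast, x, y)
  v <- rg_band(rast, band)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- v[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Write a raster as ESRI ASCII grid(s)
#'
#' Writes each band as one plain-text `.asc` file (the standard ESRI ASCII
#' grid interchange format); multiband rasters get `_b<k>` suffixes. A small
#' JSON sidecar stores the CRS tag and categorical levels.
#'
#' @param rast a `raster_grid`.
#' @param path output path; the `.asc` extension is added if missing.
#' @return invisibly, the vector of files written.
#' @export
write_raster <- function(rast, path) {
  path <- sub("\\.asc$", "", path)
  nb <- rg_nband(rast)
  files <- character(0)
  for (b in seq_len(nb)) {
    f <- if (nb == 1L) paste0(path, ".asc") else sprintf("%s_b%d.asc", path, b)
    v <- rg_band(rast, b)
    v[is.na(v)] <- rast$nodata
    con <- file(f, "w")
    writeLines(c(sprintf("ncols %d", ncol(v)),
                 sprintf("nrows %d", nrow(v)),
                 sprintf("xllcorner %.10g", rast$xmin),
                 sprintf("yllcorner %.10g", rast$ymax - nrow(v) * rast$res),
                 sprintf("cellsize %.10g", rast$res),
                 sprintf("NODATA_value %.10g", rast$nodata)), con)
    utils::write.table(format(v, trim = TRUE, digits = 10), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    close(con)
    files <- c(files, f)
  }
  meta <- list(crs = rast$crs, levels = rast$levels, bands = nb)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(files)
}

#' Read an ESRI ASCII grid written by [write_raster()]
#' @param path path to a `.asc` file (single band) or the common prefix of a
#'   multiband set.
#' @return a `raster_grid`.
#' @export
read_raster <- function(path) {
  prefix <- sub("\\.asc$", "", path)
  metaf <- paste0(prefix, ".meta.json")
  meta <- if (file.exists(metaf)) jsonlite::read_json(metaf) else list(bands = 1)
  nb <- as.integer(meta$bands %||% 1L)
  read_one <- function(f) {
    hdr <- readLines(f, n = 6L)
    kv <- strsplit(hdr, "\\s+")
    val <- function(k) as.numeric(kv[[grep(k, hdr, ignore.case = TRUE)[1]]][2])
    m <- as.matrix(utils::read.table(f, skip = 6L))
    dimnames(m) <- NULL
    m[m == val("NODATA")] <- NA
    list(m = m, xmin = val("xllcorner"), yll = val("yllcorner"),
         res = val("cellsize"), nodata = val("NODATA"))
  }
  if (nb == 1L) {
    g <- read_one(if (file.exists(path)) path else paste0(prefix, ".asc"))
    arr <- array(g$m, dim = c(dim(g$m), 1L))
  } else {
    gs <- lapply(seq_len(nb), function(b) read_one(sprintf("%s_b%d.asc", prefix, b)))
    g <- gs[[1]]
    arr <- array(NA_real_, dim = c(dim(g$m), nb))
    for (b in seq_len(nb)) arr[, , b] <- gs[[b]]$m
  }
  lv <- meta$levels
  if (!is.null(lv)) lv <- unlist(lv)
  raster_grid(arr, res = g$res, xmin = g$xmin,
              ymax = g$yll + nrow(g$m) * g$res,
              crs = meta$crs %||% "local-metric", levels = lv,
              nodata = g$nodata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a cell mask to boundary polygons
#'
#' Traces the outer boundary of the TRUE region of a logical raster into
#' closed rings by cancelling shared cell edges, so nested holes come out as
#' separate rings. Used to vectorize isopleth regions.
#'
#' @param mask a `raster_grid` whose first band is logical/0-1.
#' @return list of rings; each ring is a two-column matrix of x,y vertices
#'   (closed: first vertex repeated last).
#' @export
mask_to_polygons <- function(mask) {
  m <- rg_band(mask, 1L)
  m[is.na(m)] <- 0
  nr <- nrow(m); nc <- ncol(m); res <- mask$res
  xs <- mask$xmin + (0:nc) * res          # column edges
  ys <- mask$ymax - (0:nr) * res          # row edges (top to bottom)
  inside <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && m[r, c] == 1
  segs <- list(); k <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (m[r, c] != 1) next
    # directed edges, interior on the left (counter-clockwise exterior)
    if (!inside(r - 1, c)) { k <- k + 1L; segs[[k]] <- c(xs[c], ys[r], xs[c + 1], ys[r]) }
    if (!inside(r + 1, c)) { k <- k + 1L; segs[[k]] <- c(xs[c + 1], ys[r + 1], xs[c], ys[r + 1]) }
    if (!inside(r, c - 1)) { k <- k + 1L; segs[[k]] <- c(xs[c], ys[r + 1], xs[c], ys[r]) }
    if (!inside(r, c + 1)) { k <- k + 1L; segs[[k]] <- c(xs[c + 1], ys[r], xs[c + 1], ys[r + 1]) }
  }
  if (k == 0L) return(list())
  sm <- do.call(rbind, segs)
  from <- paste(sm[, 1], sm[, 2]); to <- paste(sm[, 3], sm[, 4])
  used <- logical(k)
  nxt <- split(seq_len(k), from)
  rings <- list()
  for (s in seq_len(k)) {
    if (used[s]) next
    ring <- list(sm[s, 1:2]); cur <- s; used[s] <- TRUE
    repeat {
      ring[[length(ring) + 1L]] <- sm[cur, 3:4]
      cand <- nxt[[to[cur]]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break
      cur <- cand[1L]; used[cur] <- TRUE
    }
    rings[[length(rings) + 1L]] <- do.call(rbind, ring)
  }
  lapply(rings, function(r) { colnames(r) <- c("x", "y"); r })
}

#' Write home-range polygons as GeoJSON
#'
#' @param ranges list of `home_range` objects (see [isopleth()]).
#' @param path output `.geojson` file.
#' @return invisibly, `path`.
#' @export
write_geojson <- function(ranges, path) {
  feats <- lapply(ranges, function(hr) {
    coords <- lapply(hr$polygons, function(r) {
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    list(type = "Feature",
         properties = list(animal_id = hr$animal_id, window = hr$window,
                           scheme = hr$scheme, level = hr$level,
                           area_km2 = hr$area_km2, n_points = hr$n_points,
                           h = hr$h),
         geometry = list(type = "MultiPolygon",
                         coordinates = lapply(coords, list)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
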