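#' Gridded habitat and detection regions
#'
#' An `scr_grid` represents a planar region tiled by non-overlapping
#' axis-aligned rectangular windows, each carrying a vector of spatial
#' covariates that are constant within the window. Habitat grids tile their
#' full rectangular extent; detection grids may cover only part of the
#' habitat (the remainder being an unsearched buffer in which activity
#' centers can still lie) but their windows must never overlap.
#'
#' All coordinates are continuous planar kilometres in a projected system;
#' geographic (long/lat) coordinates are not supported.
#'
#' @name scr_grid
NULL

new_scr_grid <- function(windows, covariates, extent, role,
                         regular = FALSE, nx = NA_integer_, ny = NA_integer_,
                         resolution = NA_real_) {
  structure(
    list(windows = windows, covariates = covariates, extent = extent,
         role = role, regular = regular, nx = nx, ny = ny,
         resolution = resolution),
    class = "scr_grid"
  )
}

#' Build a regular window grid
#'
#' Tiles a rectangular extent with square windows of side `resolution`,
#' ordered row-major from the lower-left corner (x varying fastest), and
#' attaches window-constant covariates.
#'
#' @param extent numeric of length 4, `c(xmin, ymin, xmax, ymax)` in km.
#' @param resolution window side length in km; both extent side lengths must
#'   be positive integer multiples of it.
#' @param covariates optional covariate table with one row per window in
#'   row-major window order: a matrix or data frame with named columns, or
#'   `NULL` for a grid without covariates. A `window_id` column (1-based
#'   row-major index) may be included to key rows explicitly.
#' @param role `"habitat"` or `"detection"`.
#' @return an object of class `scr_grid`.
#' @export
build_grid <- function(extent, resolution, covariates = NULL,
                       role = c("habitat", "detection")) {
  role <- match.arg(role)
  stopifnot(is.numeric(extent), length(extent) == 4)
  wx <- extent[3] - extent[1]
  wy <- extent[4] - extent[2]
  if (wx <= 0 || wy <= 0) stop("extent must have positive side lengths")
  if (resolution <= 0) stop("resolution must be positive")
  nx <- wx / resolution
  ny <- wy / resolution
  if (abs(nx - round(nx)) > 1e-8 || abs(ny - round(ny)) > 1e-8) {
    stop(sprintf(
      "extent sides (%g x %g km) are not integer multiples of resolution %g km",
      wx, wy, resolution))
  }
  nx <- as.integer(round(nx)); ny <- as.integer(round(ny))
  H <- nx * ny
  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  xmin <- extent[1] + ix * resolution
  ymin <- extent[2] + iy * resolution
  windows <- data.frame(
    window_id = seq_len(H),
    xmin = xmin, ymin = ymin,
    xmax = xmin + resolution, ymax = ymin + resolution,
    area = rep(resolution^2, H)
  )
  covariates <- normalize_covariates(covariates, H)
  new_scr_grid(windows, covariates, extent, role,
               regular = TRUE, nx = nx, ny = ny, resolution = resolution)
}

normalize_covariates <- function(covariates, H) {
  if (is.null(covariates)) {
    return(matrix(numeric(0), nrow = H, ncol = 0))
  }
  covariates <- as.data.frame(covariates)
  if ("window_id" %in% names(covariates)) {
    missing <- setdiff(seq_len(H), covariates$window_id)
    if (length(missing) > 0) {
      stop("covariate table is missing rows for window(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    covariates <- covariates[match(seq_len(H), covariates$window_id), , drop = FALSE]
    covariates$window_id <- NULL
  }
  if (nrow(covariates) != H) {
    stop(sprintf("covariate table has %d rows but the grid has %d windows",
                 nrow(covariates), H))
  }
  m <- as.matrix(covariates)
  storage.mode(m) <- "double"
  rownames(m) <- NULL
  if (any(!is.finite(m))) stop("covariates must be finite")
  m
}

#' @export
print.scr_grid <- function(x, ...) {
  cat(sprintf("<scr_grid: %s, %d windows, extent [%g, %g] x [%g, %g] km",
              x$role, nrow(x$windows),
              x$extent[1], x$extent[3], x$extent[2], x$extent[4]))
  if (x$regular) cat(sprintf(", resolution %g km", x$resolution))
  cat(sprintf(", %d covariate(s)>\n", ncol(x$covariates)))
  invisible(x)
}

#' Number of windows in a grid
#' @param grid an `scr_grid`.
#' @export
n_windows <- function(grid) nrow(grid$windows)

#' Window areas and covariate names
#' @rdname n_windows
#' @export
window_areas <- function(grid) grid$windows$area

#' @rdname n_windows
#' @export
covariate_names <- function(grid) colnames(grid$covariates)

as_point_matrix <- function(points) {
  if (is.null(dim(points))) {
    stopifnot(length(points) == 2)
    points <- matrix(points, nrow = 1)
  }
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  storage.mode(points) <- "double"
  points
}

#' Locate points in a window grid
#'
#' Maps continuous coordinates to window indices under a half-open
#' `[lower, upper)` membership convention, so that points on shared interior
#' edges belong to the window whose lower bound they touch. Points on the
#' global upper boundary of the extent are absorbed by the last window of
#' their row/column, so the grid's closed extent is fully covered without
#' double counting.
#'
#' @param grid an `scr_grid`.
#' @param points a length-2 coordinate or an `n x 2` matrix.
#' @param outside `"error"` to fail on points outside the extent (or, for a
#'   non-tiling detection grid, outside every window), `"na"` to return
#'   `NA` for them.
#' @return integer vector of 1-based window indices.
#' @export
locate_window <- function(grid, points, outside = c("error", "na")) {
  outside <- match.arg(outside)
  points <- as_point_matrix(points)
  x <- points[, 1]; y <- points[, 2]
  ext <- grid$extent
  if (grid$regular) {
    ix <- floor((x - ext[1]) / grid$resolution)
    iy <- floor((y - ext[2]) / grid$resolution)
    # absorb the global upper boundary into the last row/column
    ix[x == ext[3]] <- grid$nx - 1L
    iy[y == ext[4]] <- grid$ny - 1L
    bad <- ix < 0 | ix >= grid$nx | iy < 0 | iy >= grid$ny |
      !is.finite(x) | !is.finite(y)
    idx <- as.integer(iy * grid$nx + ix + 1L)
    idx[bad] <- NA_integer_
  } else {
    w <- grid$windows
    idx <- rep(NA_integer_, length(x))
    for (h in seq_len(nrow(w))) {
      inx <- x >= w$xmin[h] & (x < w$xmax[h] | (w$xmax[h] == ext[3] & x == w$xmax[h]))
      iny <- y >= w$ymin[h] & (y < w$ymax[h] | (w$ymax[h] == ext[4] & y == w$ymax[h]))
      hit <- inx & iny & is.na(idx)
      idx[hit] <- h
    }
  }
  if (outside == "error" && anyNA(idx)) {
    i <- which(is.na(idx))[1]
    stop(sprintf("point (%g, %g) lies outside the %s grid",
                 x[i], y[i], grid$role))
  }
  idx
}

validate_grid <- function(grid) {
  w <- grid$windows
  if (any(w$xmax <= w$xmin) || any(w$ymax <= w$ymin)) {
    stop("every window must satisfy upper > lower component-wise")
  }
  if (any(abs(w$area - (w$xmax - w$xmin) * (w$ymax - w$ymin)) > 1e-9 * w$area)) {
    stop("window area must equal the product of its side lengths")
  }
  H <- nrow(w)
  if (H > 1) {
    # pairwise open-rectangle intersection test
    for (h in seq_len(H - 1)) {
      ov <- w$xmin[(h + 1):H] < w$xmax[h] - 1e-12 &
        w$xmax[(h + 1):H] > w$xmin[h] + 1e-12 &
        w$ymin[(h + 1):H] < w$ymax[h] - 1e-12 &
        w$ymax[(h + 1):H] > w$ymin[h] + 1e-12
      if (any(ov)) {
        stop(sprintf("windows %d and %d overlap", h, h + which(ov)[1]))
      }
    }
  }
  if (grid$role == "habitat") {
    ext_area <- (grid$extent[3] - grid$extent[1]) * (grid$extent[4] - grid$extent[2])
    if (abs(sum(w$area) - ext_area) > 1e-6 * ext_area) {
      stop("habitat windows must tile the full extent")
    }
  }
  invisible(grid)
}

infer_regular <- function(grid) {
  w <- grid$windows
  sides_x <- w$xmax - w$xmin
  sides_y <- w$ymax - w$ymin
  res <- sides_x[1]
  if (any(abs(sides_x - res) > 1e-9) || any(abs(sides_y - res) > 1e-9)) {
    return(grid)
  }
  ext <- grid$extent
  nx <- round((ext[3] - ext[1]) / res)
  ny <- round((ext[4] - ext[2]) / res)
  if (nx * ny != nrow(w)) return(grid)
  ix <- round((w$xmin - ext[1]) / res)
  iy <- round((w$ymin - ext[2]) / res)
  if (!all(iy * nx + ix + 1 == seq_len(nrow(w)))) return(grid)
  grid$regular <- TRUE
  grid$nx <- as.integer(nx); grid$ny <- as.integer(ny)
  grid$resolution <- res
  grid
}

#' Read and write window grids
#'
#' CSV grids have columns `window_id, xmin, ymin, xmax, ymax` followed by one
#' column per covariate. GeoJSON grids are FeatureCollections of axis-aligned
#' rectangular Polygons whose properties carry `window_id` and the
#' covariates. Writing then reading round-trips the grid exactly, including
#' window order.
#'
#' @param path file path.
#' @param format `"csv"` or `"geojson"`; inferred from the file extension
#'   when missing.
#' @param role `"habitat"` or `"detection"`.
#' @param grid an `scr_grid`.
#' @return `read_grid` returns an `scr_grid`; `write_grid` returns `path`
#'   invisibly.
#' @export
read_grid <- function(path, format = c("auto", "csv", "geojson"),
                      role = c("habitat", "detection")) {
  format <- match.arg(format)
  role <- match.arg(role)
  if (format == "auto") {
    format <- if (grepl("\\.geojson$|\\.json$", path, ignore.case = TRUE))
      "geojson" else "csv"
  }
  if (format == "csv") {
    d <- utils::read.csv(path, check.names = FALSE)
    need <- c("window_id", "xmin", "ymin", "xmax", "ymax")
    if (!all(need %in% names(d))) {
      stop("grid CSV must have columns ", paste(need, collapse = ", "))
    }
    d <- d[order(d$window_id), , drop = FALSE]
    covnames <- setdiff(names(d), c(need, "area"))
    windows <- data.frame(
      window_id = seq_len(nrow(d)),
      xmin = d$xmin, ymin = d$ymin, xmax = d$xmax, ymax = d$ymax,
      area = (d$xmax - d$xmin) * (d$ymax - d$ymin)
    )
    covariates <- normalize_covariates(
      if (length(covnames)) d[, covnames, drop = FALSE] else NULL, nrow(d))
  } else {
    gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(gj$type) || gj$type != "FeatureCollection") {
      stop("GeoJSON grid must be a FeatureCollection")
    }
    feats <- gj$features
    rect <- lapply(seq_along(feats), function(k) {
      f <- feats[[k]]
      if (is.null(f$geometry) || f$geometry$type != "Polygon") {
        stop(sprintf("feature %d: geometry must be a Polygon", k))
      }
      ring <- f$geometry$coordinates[[1]]
      pts <- unique(do.call(rbind, lapply(ring, function(p) unlist(p)[1:2])))
      xs <- sort(unique(pts[, 1])); ys <- sort(unique(pts[, 2]))
      if (nrow(pts) != 4 || length(xs) != 2 || length(ys) != 2) {
        stop(sprintf(
          "feature %d: polygon is not an axis-aligned rectangle", k))
      }
      props <- f$properties
      c(list(xmin = xs[1], ymin = ys[1], xmax = xs[2], ymax = ys[2]),
        props)
    })
    ids <- vapply(rect, function(r) {
      if (is.null(r$window_id)) NA_real_ else as.numeric(r$window_id)
    }, numeric(1))
    ord <- if (all(is.finite(ids))) order(ids) else seq_along(rect)
    rect <- rect[ord]
    windows <- data.frame(
      window_id = seq_along(rect),
      xmin = vapply(rect, `[[`, numeric(1), "xmin"),
      ymin = vapply(rect, `[[`, numeric(1), "ymin"),
      xmax = vapply(rect, `[[`, numeric(1), "xmax"),
      ymax = vapply(rect, `[[`, numeric(1), "ymax")
    )
    windows$area <- (windows$xmax - windows$xmin) * (windows$ymax - windows$ymin)
    covnames <- setdiff(names(rect[[1]]),
                        c("xmin", "ymin", "xmax", "ymax", "window_id"))
    covariates <- if (length(covnames)) {
      m <- sapply(covnames, function(nm)
        vapply(rect, function(r) as.numeric(r[[nm]]), numeric(1)))
      normalize_covariates(matrix(m, ncol = length(covnames),
                                  dimnames = list(NULL, covnames)),
                           nrow(windows))
    } else {
      matrix(numeric(0), nrow = nrow(windows), ncol = 0)
    }
  }
  extent <- c(min(windows$xmin), min(windows$ymin),
              max(windows$xmax), max(windows$ymax))
  grid <- new_scr_grid(windows, covariates, extent, role)
  validate_grid(grid)
  grid <- infer_regular(grid)
  message(sprintf("read %s grid: %d windows, extent [%g, %g] x [%g, %g] km",
                  role, nrow(windows), extent[1], extent[3],
                  extent[2], extent[4]))
  grid
}

#' @rdname read_grid
#' @export
write_grid <- function(grid, path, format = c("auto", "csv", "geojson")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.geojson$|\\.json$", path, ignore.case = TRUE))
      "geojson" else "csv"
  }
  w <- grid$windows
  if (format == "csv") {
    out <- data.frame(window_id = w$window_id, xmin = w$xmin, ymin = w$ymin,
                      xmax = w$xmax, ymax = w$ymax)
    if (ncol(grid$covariates) > 0) {
      out <- cbind(out, as.data.frame(grid$covariates))
    }
    utils::write.csv(out, path, row.names = FALSE)
  } else {
    feats <- lapply(seq_len(nrow(w)), function(h) {
      props <- list(window_id = h)
      if (ncol(grid$covariates) > 0) {
        props <- c(props, as.list(grid$covariates[h, , drop = TRUE]))
      }
      list(
        type = "Feature",
        properties = props,
        geometry = list(
          type = "Polygon",
          coordinates = list(list(
            c(w$xmin[h], w$ymin[h]), c(w$xmax[h], w$ymin[h]),
            c(w$xmax[h], w$ymax[h]), c(w$xmin[h], w$ymax[h]),
            c(w$xmin[h], w$ymin[h])
          ))
        )
      )
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
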