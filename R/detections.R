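#' Individual detection data
#'
#' Container for SCR detection data: for each identified individual, the
#' set of continuous detection locations (km) recorded inside the detection
#' region. Individuals with zero detections never appear here — they are the
#' unobserved part of the population that the fitting methods account for.
#'
#' @param ids character vector of unique individual identifiers.
#' @param locations list of `M_i x 2` coordinate matrices, parallel to
#'   `ids`; every individual must have at least one detection.
#' @param detgrid optional detection `scr_grid`; when supplied, every
#'   location is validated to lie inside some detection window.
#' @return an object of class `scr_detections`.
#' @export
detection_data <- function(ids, locations, detgrid = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  if (length(ids) != length(locations)) {
    stop("ids and locations must have the same length")
  }
  locations <- lapply(locations, as_point_matrix)
  m <- vapply(locations, nrow, integer(1))
  if (any(m == 0)) {
    stop("observed individuals must have at least one detection: ",
         paste(ids[m == 0], collapse = ", "))
  }
  if (!is.null(detgrid)) {
    for (i in seq_along(ids)) {
      idx <- locate_window(detgrid, locations[[i]], outside = "na")
      if (anyNA(idx)) {
        j <- which(is.na(idx))[1]
        stop(sprintf(
          "individual %s: detection (%g, %g) lies outside every detection window",
          ids[i], locations[[i]][j, 1], locations[[i]][j, 2]))
      }
    }
  }
  structure(list(ids = ids, locations = locations,
                 n_observed = length(ids)),
            class = "scr_detections")
}

#' @export
print.scr_detections <- function(x, ...) {
  m <- vapply(x$locations, nrow, integer(1))
  cat(sprintf("<scr_detections: %d individuals, %d detections (per-individual range %s)>\n",
              x$n_observed, sum(m),
              if (length(m)) paste(range(m), collapse = "-") else "NA"))
  invisible(x)
}

#' Flatten detections to a data frame
#' @param x an `scr_detections`.
#' @return data frame with columns `individual_id, x, y`.
#' @export
as.data.frame.scr_detections <- function(x, ...) {
  m <- vapply(x$locations, nrow, integer(1))
  all_y <- do.call(rbind, x$locations)
  data.frame(individual_id = rep(x$ids, m),
             x = all_y[, 1], y = all_y[, 2])
}

#' Read and write detection CSV files
#'
#' Detection files have columns `individual_id, x, y` (km), one row per
#' detection; an optional `occasion` column is carried through for the
#' single-detection-per-occasion variant.
#'
#' @param path file path.
#' @param detgrid optional detection grid for validation.
#' @param x an `scr_detections`.
#' @export
read_detections <- function(path, detgrid = NULL) {
  d <- utils::read.csv(path)
  need <- c("individual_id", "x", "y")
  if (!all(need %in% names(d))) {
    stop("detections CSV must have columns ", paste(need, collapse = ", "))
  }
  ids <- unique(as.character(d$individual_id))
  locs <- lapply(ids, function(id) {
    rows <- d$individual_id == id
    cbind(d$x[rows], d$y[rows])
  })
  out <- detection_data(ids, locs, detgrid)
  message(sprintf("read detections: %d individuals, %d locations",
                  out$n_observed, nrow(d)))
  out
}

#' @rdname read_detections
#' @export
write_detections <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
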