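#' Read and write point patterns as CSV
#'
#' Patterns are stored as plain CSV with header `x,y,z`, one event per row.
#' An optional JSON sidecar (`<file>.json`) records the shape, its
#' parameters, and simulation provenance (model, seed), and is used to
#' reconstruct the shape on reading.
#'
#' @param pattern a [surface_ppp].
#' @param file CSV path.
#' @param sidecar write the JSON sidecar too?
#' @export
write_pattern <- function(pattern, file, sidecar = TRUE) {
  df <- as.data.frame(pattern$points)
  names(df) <- c("x", "y", "z")
  utils::write.csv(df, file, row.names = FALSE)
  if (sidecar) {
    meta <- list(shape = shape_config(pattern$shape),
                 metadata = pattern$metadata[
                   !vapply(pattern$metadata, is.function, logical(1))])
    jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(file)
}

#' @rdname write_pattern
#' @param shape the carrying [convex_shape]; if `NULL`, taken from the
#'   sidecar.
#' @param check verify the points lie on the shape.
#' @export
read_pattern <- function(file, shape = NULL, check = TRUE) {
  df <- utils::read.csv(file)
  stopifnot(all(c("x", "y", "z") %in% names(df)))
  meta <- list()
  side <- paste0(file, ".json")
  if (is.null(shape)) {
    if (!file.exists(side))
      stop("no shape given and no sidecar found at ", side)
    sc <- jsonlite::read_json(side, simplifyVector = TRUE)
    shape <- shape_from_config(sc$shape)
    meta <- as.list(sc$metadata)
  }
  surface_ppp(as.matrix(df[, c("x", "y", "z")]), shape, check = check,
              metadata = meta)
}

#' Shape configuration as a plain list / JSON
#'
#' `{"shape": "sphere"|"ellipsoid"|"cube", "a":..,"b":..,"c":..,"l":..,
#' "radius":..}`.
#'
#' @param shape a [convex_shape].
#' @export
shape_config <- function(shape) {
  c(list(shape = shape$name), shape$params)
}

#' @rdname shape_config
#' @param config list (or JSON file path) with a `shape` entry.
#' @export
shape_from_config <- function(config) {
  if (is.character(config) && length(config) == 1 && file.exists(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  switch(config$shape,
    sphere = cs_sphere(if (!is.null(config$radius)) config$radius
                       else if (!is.null(config$a)) config$a else 1),
    ellipsoid = cs_ellipsoid(config$a, config$b, config$c),
    cube = cs_cube(config$l),
    stop("unknown shape: ", config$shape))
}
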