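## File I/O: kymographs as 16-bit grayscale TIFF or CSV with a YAML
## metadata sidecar; force-distance tables as CSV; result bundles as JSON.

sidecarPath <- function(path) {
  paste0(sub("\\.[A-Za-z]+$", "", path), ".meta.yaml")
}

#' Write a kymograph to disk
#'
#' Counts are written either as a single-plane 16-bit grayscale TIFF
#' (`.tif`/`.tiff`) or as a comma-delimited integer matrix (`.csv`), rows =
#' scan lines. Pixel size and line period go to a YAML sidecar
#' (`<stem>.meta.yaml`). The round trip through either format is
#' bit-identical.
#'
#' @param kymo a [Kymograph-class].
#' @param path output file; the extension selects the format.
#' @return `path`, invisibly.
#' @export
writeKymograph <- function(kymo, path) {
  stopifnot(is(kymo, "Kymograph"))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("tif", "tiff")) {
    if (max(kymo@counts) > 65535)
      stop("counts exceed the 16-bit TIFF range")
    tiff::writeTIFF(kymo@counts / 65535, path, bits.per.sample = 16L)
  } else if (ext == "csv") {
    utils::write.table(kymo@counts, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else stop("unsupported kymograph format: .", ext)
  meta <- list(pixel_size_nm = kymo@pixelSize,
               line_period_s = kymo@linePeriod)
  if (!is.null(kymo@metadata$optics))
    meta$laser_power_uW <- kymo@metadata$optics@laserPower
  yaml::write_yaml(meta, sidecarPath(path))
  invisible(path)
}

#' Read a kymograph from disk
#'
#' Accepts a single-plane grayscale TIFF or a delimited integer matrix,
#' with pixel size and line period from the YAML sidecar written by
#' [writeKymograph()] (or passed explicitly). Multi-plane or RGB TIFFs and
#' negative or non-integer values are rejected.
#'
#' @param path input file (`.tif`/`.tiff`/`.csv`).
#' @param pixelSize,linePeriod metadata overrides (nm, s); required when no
#'   sidecar exists.
#' @return A [Kymograph-class].
#' @export
readKymograph <- function(path, pixelSize = NULL, linePeriod = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (length(img) > 1)
      stop("multi-plane TIFF: kymographs must be single-plane grayscale")
    img <- img[[1]]
    if (length(dim(img)) == 3)
      stop("RGB/multi-channel TIFF: kymographs must be single-plane grayscale")
    cts <- img
  } else if (ext == "csv") {
    cts <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(cts) <- NULL
    if (!is.numeric(cts)) stop("CSV kymograph must be numeric")
    if (any(cts < 0)) stop("negative photon counts in CSV kymograph")
    if (any(cts != round(cts)))
      stop("non-integer photon counts in CSV kymograph")
  } else stop("unsupported kymograph format: .", ext)
  sc <- sidecarPath(path)
  meta <- if (file.exists(sc)) yaml::read_yaml(sc) else list()
  ps <- pixelSize %||% meta$pixel_size_nm
  lp <- linePeriod %||% meta$line_period_s
  missing <- c(if (is.null(ps)) "pixel_size_nm",
               if (is.null(lp)) "line_period_s")
  if (length(missing))
    stop("missing kymograph metadata (no sidecar ", basename(sc),
         " and no override): ", paste(missing, collapse = ", "))
  kymograph(cts, pixelSize = ps, linePeriod = lp,
            metadata = meta[setdiff(names(meta),
                                    c("pixel_size_nm", "line_period_s"))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write force-distance curves as CSV
#'
#' Two-column tables `distance_um`, `force_pN` plus a `label` column
#' (`free` or `compacted`).
#'
#' @param fd a [ForceDistanceCurve-class].
#' @param path CSV file.
#' @return `readForceDistance()` returns a [ForceDistanceCurve-class];
#'   `writeForceDistance()` returns `path` invisibly.
#' @export
writeForceDistance <- function(fd, path) {
  utils::write.csv(as.data.frame(fd), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeForceDistance
#' @export
readForceDistance <- function(path) {
  df <- utils::read.csv(path)
  need <- c("distance_um", "force_pN")
  if (!all(need %in% names(df)))
    stop("force-distance CSV must have columns: ",
         paste(need, collapse = ", "))
  lab <- if ("label" %in% names(df)) as.character(df$label[1]) else "free"
  forceDistanceCurve(df$distance_um, df$force_pN, label = lab)
}

#' Write a result bundle as JSON
#'
#' Serializes a [runPipeline()] bundle (or any list of results) as JSON.
#' The accompanying schema is shipped at
#' `system.file("schema", "result-bundle.schema.json", package = "KymoQuant")`.
#'
#' @param bundle a named list.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
writeResultBundle <- function(bundle, path) {
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Check a result bundle against the shipped schema
#'
#' Lightweight structural validation: verifies that every property the
#' schema marks as required is present (recursively for object-valued
#' properties).
#'
#' @param bundle a named list, or the path to a bundle JSON file.
#' @return `TRUE` invisibly, or an error naming the missing fields.
#' @export
validateBundle <- function(bundle) {
  if (is.character(bundle)) bundle <- jsonlite::read_json(bundle)
  schema <- jsonlite::read_json(system.file("schema",
    "result-bundle.schema.json", package = "KymoQuant"))
  checkNode <- function(node, sch, where) {
    req <- unlist(sch$required)
    miss <- setdiff(req, names(node))
    if (length(miss))
      stop("bundle is missing required field(s) at ", where, ": ",
           paste(miss, collapse = ", "))
    for (nm in intersect(names(sch$properties), names(node))) {
      p <- sch$properties[[nm]]
      if (identical(p$type, "object"))
        checkNode(node[[nm]], p, paste0(where, "/", nm))
    }
  }
  checkNode(bundle, schema, "")
  invisible(TRUE)
}
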