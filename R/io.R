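# Table schemas: plain CSV with unit-suffixed headers. Columns listed here
# are required (the unit suffix is part of the name, so a header without it
# is rejected); unknown extra columns are preserved with a warning.
table_schemas <- list(
  trajectory = list(
    cols = c(track_id = "character", species = "character",
             frame = "numeric", t_s = "numeric", x_cm = "numeric",
             y_cm = "numeric", z_cm = "numeric")),
  pixel_track = list(
    cols = c(frame = "numeric", u_px = "numeric", v_px = "numeric")),
  feeding = list(
    cols = c(fish_id = "character", species = "character",
             quadrat = "character", TL_mm = "numeric", entry_s = "numeric",
             exit_s = "numeric", t_s = "numeric", substrate = "character",
             x_cm = "numeric", y_cm = "numeric", z_cm = "numeric")),
  cover = list(
    cols = c(quadrat = "character", category = "character",
             cells = "numeric")),
  respirometry = list(
    cols = c(mass_g = "numeric", smr_mgO2_d = "numeric"))
)

validate_table <- function(df, type, file = "<data>") {
  schema <- table_schemas[[type]]
  if (is.null(schema)) stop("unknown table type: ", type)
  need <- names(schema$cols)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(file, ": schema mismatch for '", type, "' table.\n  expected: ",
         paste(need, collapse = ", "), "\n  found:    ",
         paste(names(df), collapse = ", "),
         "\n  missing:  ", paste(miss, collapse = ", "),
         " (unit suffixes are part of the column name)")
  extra <- setdiff(names(df), need)
  if (length(extra) && !all(startsWith(extra, "truth_")))
    warning(file, ": unknown column(s) preserved: ",
            paste(setdiff(extra, extra[startsWith(extra, "truth_")]),
                  collapse = ", "))
  for (cl in need[schema$cols == "numeric"]) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (length(bad))
      stop(file, ": malformed numeric value(s) in column '", cl,
           "' at data row(s) ", paste(utils::head(bad, 5), collapse = ", "))
    df[[cl]] <- v
  }
  df
}

#' Read / write the pipeline's delimited tables
#'
#' Plain CSV with explicit, unit-suffixed headers (`t_s`, `x_cm`, `TL_mm`,
#' ...). On read, the header is validated against the schema of the table
#' type: missing or un-suffixed required columns are rejected with the
#' expected-vs-found column lists, malformed numeric cells are rejected with
#' their row numbers, and unknown extra columns are preserved with a
#' warning. `read(write(x))` is the identity for every table type.
#'
#' @param path file path.
#' @param type one of `"trajectory"`, `"pixel_track"`, `"feeding"`,
#'   `"cover"`, `"respirometry"`.
#' @param fps for `type = "trajectory"`, the acquisition rate attached to the
#'   returned [trajectory3d()].
#' @return the validated data frame (a [trajectory3d()] for trajectories).
#' @export
read_table_csv <- function(path, type, fps = 60) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- validate_table(df, type, file = path)
  if (type == "trajectory") df <- trajectory3d(df, fps = fps)
  df
}

#' @param x data frame to write (validated against the schema first).
#' @rdname read_table_csv
#' @export
write_table_csv <- function(x, path, type) {
  x <- validate_table(as.data.frame(x), type)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a stereo rig configuration
#'
#' YAML (or JSON) file mirroring the standard pinhole+distortion parameter
#' set: per-camera `fx`, `fy`, `cx`, `cy`, `k1`, `k2`, `p1`, `p2`, plus the
#' rig `rotation` (row-major 3x3), `translation` (cm) and `image_size`.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return a [camera_rig()].
#' @export
read_rig <- function(path) {
  if (!file.exists(path)) stop("rig config not found: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  rot <- if (is.matrix(cfg$rotation)) cfg$rotation   # JSON readers simplify
         else matrix(unlist(cfg$rotation), 3, 3, byrow = TRUE)
  camera_rig(cfg$left, cfg$right,
             rotation = rot,
             translation = unlist(cfg$translation),
             image_size = unlist(cfg$image_size))
}

#' @param rig a [camera_rig()].
#' @rdname read_rig
#' @export
write_rig <- function(rig, path) {
  stopifnot(inherits(rig, "camera_rig"))
  obj <- list(left = rig$left, right = rig$right,
              rotation = lapply(1:3, function(i) as.numeric(rig$rotation[i, ])),
              translation = as.numeric(rig$translation),
              image_size = as.numeric(rig$image_size))
  if (grepl("\\.json$", path))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' JSON record of the seed, parameters and package version of a pipeline
#' run; together with the inputs it suffices to reproduce the run.
#'
#' @param config the pipeline configuration list.
#' @param path output path.
#' @param extra optional named list of bookkeeping counters.
#' @export
write_manifest <- function(config, path, extra = list()) {
  manifest <- list(
    package = "reefodba",
    version = as.character(utils::packageVersion("reefodba")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    parameter_hash = param_hash(config),
    config = config)
  manifest <- c(manifest, extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# order-invariant digest of the configuration: polynomial rolling hash of the
# deparsed, name-sorted config (stable across sessions; no digest dependency)
param_hash <- function(config) {
  cfg <- config[order(names(config))]
  s <- paste(deparse(cfg, control = "all"), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
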