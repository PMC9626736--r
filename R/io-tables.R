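# Tabular and JSON I/O: voltage clouds and fiducials as CSV, registrations
# as JSON, score tables as CSV, run configuration as YAML. Units are mm and
# mV throughout, declared in the column names.

#' Read and write EAM voltage clouds (CSV)
#'
#' Columns `x_mm`, `y_mm`, `z_mm`, `voltage_mV`. Negative voltages are
#' rejected on read with the offending row number.
#'
#' @param cloud an [EAMCloud-class].
#' @param path CSV file path.
#' @return `readEAMCloud()` returns an [EAMCloud-class].
#' @export
writeEAMCloud <- function(cloud, path) {
  stopifnot(is(cloud, "EAMCloud"))
  df <- data.frame(x_mm = cloud@points[, 1], y_mm = cloud@points[, 2],
                   z_mm = cloud@points[, 3], voltage_mV = cloud@voltage)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEAMCloud
#' @export
readEAMCloud <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x_mm", "y_mm", "z_mm", "voltage_mV")
  if (!all(need %in% names(df)))
    stop("cloud CSV must have columns ", paste(need, collapse = ", "), ": ", path)
  bad <- which(df$voltage_mV < 0)
  if (length(bad))
    stop("negative voltage at row ", bad[1], " of ", path)
  new("EAMCloud", points = as.matrix(df[, c("x_mm", "y_mm", "z_mm")]),
      voltage = df$voltage_mV)
}

#' Read and write fiducial sets (CSV)
#'
#' Long format with two rows per landmark: columns `name`, `frame` ("eam" or
#' "spect"), `x`, `y`, `z` (mm), `role` ("primary"/"secondary"). Reading
#' pairs the two frames by name.
#'
#' @param fiducials a [FiducialSet-class].
#' @param path CSV file path.
#' @return `readFiducials()` returns a [FiducialSet-class].
#' @export
writeFiducials <- function(fiducials, path) {
  stopifnot(is(fiducials, "FiducialSet"))
  df <- rbind(
    data.frame(name = fiducials@name, frame = "eam",
               x = fiducials@source[, 1], y = fiducials@source[, 2],
               z = fiducials@source[, 3], role = fiducials@role),
    data.frame(name = fiducials@name, frame = "spect",
               x = fiducials@target[, 1], y = fiducials@target[, 2],
               z = fiducials@target[, 3], role = fiducials@role)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFiducials
#' @export
readFiducials <- function(path) {
  df <- utils::read.csv(path)
  need <- c("name", "frame", "x", "y", "z", "role")
  if (!all(need %in% names(df)))
    stop("fiducial CSV must have columns ", paste(need, collapse = ", "), ": ", path)
  eam <- df[df$frame == "eam", ]
  sp <- df[df$frame == "spect", ]
  if (!setequal(eam$name, sp$name))
    stop("unpaired fiducials in ", path)
  sp <- sp[match(eam$name, sp$name), ]
  new("FiducialSet", source = as.matrix(eam[, c("x", "y", "z")]),
      target = as.matrix(sp[, c("x", "y", "z")]),
      role = eam$role, name = eam$name)
}

#' Read and write a fitted registration (JSON)
#'
#' Stores the rigid rotation (row-major), translation and scale, plus the
#' TPS control points, weights, affine part and stiffness when a nonrigid
#' stage is present.
#'
#' @param registration a [RegistrationPipeline-class].
#' @param path JSON file path.
#' @return `readRegistration()` returns a [RegistrationPipeline-class].
#' @export
writeRegistration <- function(registration, path) {
  stopifnot(is(registration, "RegistrationPipeline"))
  out <- list(
    direction = "eam_to_spect",
    rigid = list(rotation_row_major = as.numeric(t(registration@rigid@rotation)),
                 translation_mm = registration@rigid@translation,
                 scale = registration@rigid@scale)
  )
  if (!is.null(registration@tps)) {
    tps <- registration@tps
    out$tps <- list(kernel = "U(r)=r",
                    control_points_mm = tps@controlPoints,
                    weights = tps@weights,
                    affine = tps@affine,
                    stiffness = tps@stiffness)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRegistration
#' @export
readRegistration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid <- new("RigidTransform",
               rotation = matrix(x$rigid$rotation_row_major, 3, 3, byrow = TRUE),
               translation = x$rigid$translation_mm,
               scale = x$rigid$scale)
  tps <- NULL
  if (!is.null(x$tps)) {
    toMat <- function(m) {
      if (is.matrix(m)) m else do.call(rbind, lapply(m, as.numeric))
    }
    tps <- new("TPSWarp",
               controlPoints = toMat(x$tps$control_points_mm),
               weights = toMat(x$tps$weights),
               affine = toMat(x$tps$affine),
               stiffness = x$tps$stiffness)
  }
  new("RegistrationPipeline", rigid = rigid, tps = tps)
}

#' Read and write segment score tables (CSV)
#'
#' @param table a score table from [segmentScores()].
#' @param path CSV file path.
#' @return `readScoreTable()` returns the data.frame.
#' @export
writeScoreTable <- function(table, path) {
  out <- table
  # full double precision so thresholds sitting exactly on an observed score
  # mean classify identically after a round-trip
  for (col in c("mean", "sd"))
    out[[col]] <- ifelse(is.na(table[[col]]), NA, sprintf("%.17g", table[[col]]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeScoreTable
#' @export
readScoreTable <- function(path) {
  df <- utils::read.csv(path)
  need <- c("subject", "segment", "modality", "n", "mean", "sd",
            "heterogeneous", "imputed", "excluded")
  if (!all(need %in% names(df)))
    stop("score table CSV missing columns: ", path)
  df
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [cohortConfig()]
#' defaults.
#'
#' @param path YAML file path.
#' @return a config list as produced by [cohortConfig()].
#' @export
readRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  x <- lapply(x, function(el) if (is.list(el)) unlist(el) else el)
  known <- names(formals(cohortConfig))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown config field(s) in ", path, ": ", paste(bad, collapse = ", "))
  do.call(cohortConfig, x)
}

#' @rdname readRunConfig
#' @param config a config list from [cohortConfig()].
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
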