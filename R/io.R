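#' Read and write the package's plain-text interchange formats
#'
#' All artefacts are exchanged as delimited text plus JSON sidecars so
#' that runs are diffable and language-agnostic: training sets and
#' trajectories as CSV, manifests / scaling records / expression
#' constants as JSON, expressions as prefix-notation strings.
#'
#' @param data a [training_set()] tibble.
#' @param path file path.
#' @name guidedtps-io
NULL

#' @rdname guidedtps-io
#' @export
write_training_set <- function(data, path) {
  readr::write_csv(as_tibble(data), path)
  invisible(path)
}

#' @rdname guidedtps-io
#' @export
read_training_set <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname guidedtps-io
#' @param traj a `trajectory` or [tps_path()].
#' @param manifest optional named list written as a JSON sidecar
#'   (`<path>.json`): engine parameters, seed, terminal state, and any
#'   provenance the caller supplies.
#' @export
write_trajectory <- function(traj, path, manifest = NULL) {
  df <- as_tibble(traj)
  readr::write_csv(df, path)
  if (!is.null(manifest)) {
    jsonlite::write_json(manifest, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname guidedtps-io
#' @export
read_trajectory <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname guidedtps-io
#' @param run a `guided_tps_run`.
#' @param dir output directory (created if missing): one CSV per
#'   collected path, the ledger and records CSVs, and an ensemble
#'   manifest JSON with weights, acceptance log and seeds.
#' @export
write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(run$ledger, file.path(dir, "ledger.csv"))
  if (nrow(run$records) > 0) {
    readr::write_csv(run$records, file.path(dir, "records.csv"))
  }
  for (i in seq_along(run$paths)) {
    readr::write_csv(as_tibble(run$paths[[i]]),
                     file.path(dir, sprintf("path_%04d.csv", i)))
  }
  manifest <- c(run$settings,
                list(n_paths_collected = length(run$paths),
                     n_tp_generated = sum(run$ledger$generated),
                     n_accepted = sum(run$ledger$accepted),
                     package_version =
                       as.character(utils::packageVersion("guidedtps"))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname guidedtps-io
#' @param scaling a scaling record from [scale_features()].
#' @export
write_scaling <- function(scaling, path) {
  enc <- scaling
  for (f in c("min", "span", "divisor")) {
    if (!is.null(enc[[f]])) enc[[f]] <- as.list(enc[[f]])
  }
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname guidedtps-io
#' @export
read_scaling <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(rec$min)) rec$min <- unlist(rec$min)
  if (!is.null(rec$span)) rec$span <- unlist(rec$span)
  if (!is.null(rec$divisor)) rec$divisor <- unlist(rec$divisor)
  rec
}

#' @rdname guidedtps-io
#' @param expr an [sr_expr][sr_var] expression.
#' @export
write_expression <- function(expr, path) {
  writeLines(sr_serialize(expr), path)
  invisible(path)
}

#' @rdname guidedtps-io
#' @export
read_expression <- function(path) {
  sr_deserialize(paste(readLines(path), collapse = " "))
}

#' @rdname guidedtps-io
#' @param importance a [permutation_importance()] table.
#' @export
write_importance <- function(importance, path) {
  readr::write_csv(importance, path)
  invisible(path)
}

#' @rdname guidedtps-io
#' @param cloud a 3D point tibble.
#' @param comment XYZ comment line.
#' @export
write_xyz <- function(cloud, path, comment = "point cloud") {
  cloud <- as_tibble(cloud)
  lines <- c(as.character(nrow(cloud)), comment,
             sprintf("X %.10f %.10f %.10f", cloud$x, cloud$y, cloud$z))
  writeLines(lines, path)
  invisible(path)
}
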