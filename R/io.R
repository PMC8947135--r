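#' CSV and configuration plumbing
#'
#' All tables are written as UTF-8 comma-separated files with '.' decimals,
#' a mandatory header row, and a provenance comment header (package
#' version, seed, config hash) so every artifact can be traced to the
#' configuration that produced it.
#'
#' @name cli_io
NULL

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp)  # scratch only; hashed then removed
  unname(tools::md5sum(tmp))
}

#' Write a table with a provenance header
#'
#' @param df Data frame.
#' @param path Output path.
#' @param seed Seed recorded in the header.
#' @param config Configuration object; its hash is recorded.
#' @export
write_csv_provenance <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# flighttunnel %s",
                     as.character(utils::packageVersion("flighttunnel"))), con)
  writeLines(sprintf("# seed: %s", format(seed)), con)
  if (!is.null(config))
    writeLines(sprintf("# config_hash: %s", config_hash(config)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline CSV, skipping provenance comments
#'
#' @param path File path.
#' @param required Character vector of required column names; a missing
#'   column is an error naming it.
#' @return Data frame.
#' @export
read_pipeline_csv <- function(path, required = NULL) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing))
      stop("malformed CSV ", path, ": missing column(s) ",
           paste(missing, collapse = ", "))
  }
  df
}

#' Write / read per-camera detections
#'
#' Schema: \code{flight_id}, \code{camera_id}, \code{frame}, \code{u},
#' \code{v}, \code{area}.
#' @param detections Data frame in the schema above.
#' @param path File path.
#' @param ... Passed to \code{\link{write_csv_provenance}}.
#' @export
write_detections_csv <- function(detections, path, ...) {
  cols <- c("flight_id", "camera_id", "frame", "u", "v", "area")
  write_csv_provenance(detections[, cols], path, ...)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  read_pipeline_csv(path, required = c("flight_id", "camera_id", "frame",
                                       "u", "v", "area"))
}

#' Read a run configuration from YAML or JSON
#'
#' Keys override \code{\link{behavior_config}} arguments; unknown keys are
#' an error.
#' @param path A \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A \code{behavior_config}.
#' @export
read_behavior_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(behavior_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$p_within)) raw$p_within <- unlist(raw$p_within)
  if (!is.null(raw$altitude_shift_high))
    raw$altitude_shift_high <- unlist(raw$altitude_shift_high)
  do.call(behavior_config, raw)
}

#' Flatten an experiment's detections into one table
#'
#' @param experiment A \code{flight_experiment}.
#' @return Data frame in the detections CSV schema.
#' @export
experiment_detections <- function(experiment) {
  rows <- lapply(experiment$flights, function(fl) {
    if (is.null(fl$detections)) return(NULL)
    fid <- paste0(fl$flight$cond$bee_id, "_f", fl$flight$cond$flight_number)
    d <- rbind(fl$detections$a, fl$detections$b)
    cbind(flight_id = fid, d[, c("camera_id", "frame", "u", "v", "area")])
  })
  do.call(rbind, rows)
}
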