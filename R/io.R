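# CSV contracts. All files are plain comma-separated text; lines starting
# with `#` are comments (the force file may carry a `# setup: <dialect>`
# header).

read_csv_commented <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header_comments <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("no data rows in ", path)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  attr(df, "comments") <- header_comments
  df
}

#' Read sonomicrometry distance traces from CSV
#'
#' Expected header: `time_s` followed by pair columns named
#' `"<fixedID>-<brainID>"` (e.g. `F1-B1`), distances in mm. Comment lines
#' start with `#`. Non-numeric cells are masked (with a counted warning),
#' preserving the time base.
#'
#' @param path CSV file path.
#' @return An uncalibrated `distance_traces`.
#' @export
read_distance_csv <- function(path) {
  df <- read_csv_commented(path)
  if (!"time_s" %in% names(df)) stop("missing `time_s` column in ", path)
  if (anyDuplicated(names(df))) {
    stop("duplicated column(s) in ", path, ": ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  }
  pair_cols <- setdiff(names(df), "time_s")
  if (!length(pair_cols)) stop("no pair columns in ", path)
  bad <- pair_cols[!grepl("^[A-Za-z0-9_]+-[A-Za-z0-9_]+$", pair_cols)]
  if (length(bad)) {
    stop("column(s) not named '<fixedID>-<brainID>': ",
         paste(bad, collapse = ", "))
  }
  time <- suppressWarnings(as.numeric(df$time_s))
  if (any(!is.finite(time))) stop("non-numeric time values in ", path)
  if (any(diff(time) <= 0)) stop("`time_s` must be strictly increasing in ",
                                 path)
  d <- suppressWarnings(
    vapply(df[pair_cols], function(col) as.numeric(col), numeric(nrow(df)))
  )
  d <- matrix(d, nrow = nrow(df), dimnames = list(NULL, pair_cols))
  n_bad <- sum(!is.finite(d))
  if (n_bad > 0) {
    warning(n_bad, " non-numeric distance cell(s) masked in ",
            basename(path))
  }
  distance_traces(time, d)
}

#' Write distance traces to CSV
#'
#' Inverse of [read_distance_csv()]; masked samples are written as `NaN`.
#'
#' @param d A `distance_traces`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(d, path) {
  stopifnot(inherits(d, "distance_traces"))
  m <- d$d
  m[!d$mask] <- NaN
  df <- data.frame(time_s = d$time, check.names = FALSE)
  df[colnames(m)] <- as.data.frame(m)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a traction-force trace from CSV
#'
#' Expected columns `time_s,force_N`. The setup dialect (manual hand gage
#' at 10 Hz, or automatic testing machine at 1000 Hz) is taken from an
#' optional `# setup: manual|automatic` comment line, or detected from the
#' median sampling interval (<= 2 ms: automatic; >= 50 ms: manual).
#'
#' @param path CSV file path.
#' @param dialect `"manual"`, `"automatic"` or `"auto"` (detect).
#' @return A `force_trace` with `setup` and `sample_rate` attributes.
#' @export
read_force_csv <- function(path, dialect = c("auto", "manual", "automatic")) {
  dialect <- match.arg(dialect)
  df <- read_csv_commented(path)
  if (!all(c("time_s", "force_N") %in% names(df))) {
    stop("force CSV must have columns time_s,force_N: ", path)
  }
  time <- as.numeric(df$time_s)
  if (any(diff(time) <= 0)) stop("negative or zero time step in ", path)
  if (dialect == "auto") {
    hdr <- grep("^#\\s*setup:", attr(df, "comments"), value = TRUE)
    if (length(hdr)) {
      dialect <- trimws(sub("^#\\s*setup:", "", hdr[1]))
      if (!dialect %in% c("manual", "automatic")) {
        stop("unknown setup dialect '", dialect, "' in ", path)
      }
    } else {
      dt <- stats::median(diff(time))
      dialect <- if (dt <= 0.002) "automatic"
      else if (dt >= 0.05) "manual"
      else stop("ambiguous force dialect (median step ", signif(dt, 3),
                " s) and no `# setup:` header in ", path)
    }
  }
  out <- data.frame(time_s = time, force_N = as.numeric(df$force_N))
  attr(out, "setup") <- dialect
  attr(out, "sample_rate") <- 1 / stats::median(diff(time))
  class(out) <- c("force_trace", "data.frame")
  out
}

#' Write a force trace to CSV
#'
#' @param force A `force_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_force_csv <- function(force, path) {
  stopifnot(inherits(force, "force_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# setup: ", attr(force, "setup")), con)
  utils::write.csv(as.data.frame(force)[c("time_s", "force_N")], con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read reference crystal geometry
#'
#' CSV columns `id,role,region,x_mm,y_mm,z_mm`, or a JSON object with a
#' `crystals` array carrying the same fields. Both encodings parse to the
#' identical geometry.
#'
#' @param path CSV or JSON file path.
#' @param provenance `"CT"` (default) or `"synthetic-truth"`.
#' @return A `reference_geometry`.
#' @export
read_reference <- function(path, provenance = "CT") {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    df <- as.data.frame(obj$crystals)
  } else {
    df <- read_csv_commented(path)
  }
  req <- c("id", "role", "region", "x_mm", "y_mm", "z_mm")
  if (!all(req %in% names(df))) {
    stop("reference file must have columns ", paste(req, collapse = ","),
         ": ", path)
  }
  geom <- data.frame(id = df$id, role = df$role, region = df$region,
                     x = as.numeric(df$x_mm), y = as.numeric(df$y_mm),
                     z = as.numeric(df$z_mm))
  reference_geometry(geom, provenance = provenance)
}

#' Write reference geometry to CSV
#'
#' @param ref A `reference_geometry` (or `crystal_layout`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_csv <- function(ref, path) {
  df <- as.data.frame(ref)
  out <- data.frame(id = df$id, role = df$role, region = df$region,
                    x_mm = df$x, y_mm = df$y, z_mm = df$z)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic experiment as a fixture directory
#'
#' Writes `distances.csv`, `force.csv`, `reference.csv`, `truth.json`
#' (ground-truth direction, compliances, rest separations and per-pair
#' channel biases) and `config.yaml` (full provenance including seeds), so
#' that a synthetic experiment can be re-read and processed exactly like a
#' recorded one.
#'
#' @param experiment A `vad_experiment` from [simulate_experiment()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(experiment, dir) {
  stopifnot(inherits(experiment, "vad_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_distance_csv(experiment$distances, file.path(dir, "distances.csv"))
  write_force_csv(experiment$force, file.path(dir, "force.csv"))
  write_reference_csv(experiment$reference, file.path(dir, "reference.csv"))
  truth <- experiment$truth
  jsonlite::write_json(
    list(force_direction = truth$model$force_direction,
         rigid_compliance_mm_per_N = truth$model$rigid_compliance,
         per_crystal_compliance_mm_per_N =
           as.list(truth$model$per_crystal_compliance),
         pair_D0_mm = as.list(truth$pair_D0),
         channel_bias = as.list(experiment$bias),
         n_injected_outliers = nrow(experiment$outliers)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(experiment$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a fixture directory back as pipeline inputs
#'
#' @param dir Directory written by [write_fixture()] (or assembled from
#'   recorded data in the same layout).
#' @return List with `distances`, `force`, `reference`, and, when present,
#'   `truth` and `config`.
#' @export
read_fixture <- function(dir) {
  out <- list(
    distances = read_distance_csv(file.path(dir, "distances.csv")),
    force = read_force_csv(file.path(dir, "force.csv")),
    reference = read_reference(file.path(dir, "reference.csv"),
                               provenance = "synthetic-truth")
  )
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) out$truth <- jsonlite::fromJSON(tj)
  cy <- file.path(dir, "config.yaml")
  if (file.exists(cy)) out$config <- yaml::read_yaml(cy)
  out
}
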