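#' Trace file formats
#'
#' Traces are tab-separated values with a `#`-prefixed `key: value` header
#' declaring `format_version`, `kind` (`force_ramp` or `force_clamp`), the
#' construct label and the protocol fields. Units are fixed: seconds,
#' nanometres, piconewtons. Ramp files conventionally end in `.fec.tsv`,
#' clamp files in `.fct.tsv`, titration count tables in `.counts.tsv`.
#'
#' @name trace-formats
#' @keywords internal
NULL

.format_version <- "1"

.header_lines <- function(kind, meta) {
  keys <- c(format_version = .format_version, kind = kind, meta)
  paste0("# ", names(keys), ": ", unname(keys))
}

.parse_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  if (length(hdr) == 0) {
    abort("Missing `#` header: not a tweezfold trace file.",
          class = "tweezfold_format_error")
  }
  kv <- sub("^#\\s*", "", hdr)
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  meta <- as.list(setNames(vals, keys))
  if (is.null(meta$format_version) || is.null(meta$kind)) {
    abort("Header must declare `format_version` and `kind`.",
          class = "tweezfold_format_error")
  }
  meta
}

#' Write a trajectory to a headered TSV file
#'
#' @param trace A `force_ramp_trace` or `force_clamp_trace` tibble (as
#'   produced by [simulate_force_ramp()] / [simulate_force_clamp()] or
#'   [read_trace()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "force_ramp_trace")) {
    proto <- attr(trace, "protocol")
    meta <- c(construct = attr(trace, "construct") %||% "unknown",
              vapply(proto, function(v) format(v, digits = 15), character(1)))
    hdr <- .header_lines("force_ramp", meta)
    body <- as.data.frame(trace)[, c("time", "extension", "force",
                                     "cycle_id", "segment")]
  } else if (inherits(trace, "force_clamp_trace")) {
    meta <- c(construct = attr(trace, "construct") %||% "unknown",
              setpoint_force = format(attr(trace, "setpoint_force"),
                                      digits = 15),
              sample_rate = format(attr(trace, "sample_rate"), digits = 15))
    hdr <- .header_lines("force_clamp", meta)
    cols <- intersect(c("time", "extension", "force"), names(trace))
    body <- as.data.frame(trace)[, cols]
  } else {
    abort("`trace` must be a force_ramp_trace or force_clamp_trace.",
          class = "tweezfold_invalid_input")
  }
  writeLines(hdr, path)
  readr::write_tsv(body, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

.validate_times <- function(time, n_header, group_offsets = NULL) {
  bad <- which(diff(time) <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "Time must be strictly increasing: violation at data line %d (file line %d).",
      bad[1] + 1L, bad[1] + 1L + n_header + 1L),
      class = "tweezfold_validation_error")
  }
}

.validate_spacing <- function(df, sample_rate, n_header) {
  grp <- if (all(c("cycle_id", "segment") %in% names(df))) {
    paste(df$cycle_id, df$segment)
  } else rep("all", nrow(df))
  dt <- 1 / sample_rate
  for (g in unique(grp)) {
    tg <- df$time[grp == g]
    if (length(tg) < 2) next
    d <- diff(tg)
    if (any(abs(d - dt) / dt > 1e-6)) {
      abort(sprintf(
        "Sample spacing in group '%s' deviates from 1/sample_rate by more than 1 ppm.",
        g), class = "tweezfold_validation_error")
    }
  }
}

#' Read a trajectory file
#'
#' Parses the `#` header, reads the TSV body, and validates the trace
#' invariants: strictly increasing time (violations are reported with their
#' line number), uniform sample spacing within each ramp segment (1 ppm
#' tolerance), and for clamp traces with a recorded force column, a
#' setpoint drift of at most 0.1 pN (range).
#'
#' @param path Path to a `.fec.tsv` or `.fct.tsv` file.
#' @return A `force_ramp_trace` or `force_clamp_trace` tibble with metadata
#'   attributes restored.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "tweezfold_io_error")
  }
  lines <- readLines(path, n = 200L)
  meta <- .parse_header(lines)
  n_header <- sum(grepl("^#", lines))
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (nrow(df) == 0) {
    abort("Trace file has no data rows.", class = "tweezfold_format_error")
  }

  if (meta$kind == "force_ramp") {
    need <- c("time", "extension", "force", "cycle_id", "segment")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      abort(paste("Ramp trace missing column(s):", paste(miss, collapse = ", ")),
            class = "tweezfold_format_error")
    }
    sr <- as.numeric(meta$sample_rate)
    .validate_times(df$time, n_header)
    if (is.finite(sr)) .validate_spacing(df, sr, n_header)
    proto_fields <- c("pull_velocity", "sample_rate", "refold_hold_force",
                      "refold_hold_time", "min_force", "max_force",
                      "temperature", "trap_stiffness", "handle_contour",
                      "handle_persistence", "protein_persistence")
    proto <- NULL
    if (all(proto_fields %in% names(meta))) {
      proto <- do.call(pulling_protocol,
                       lapply(meta[proto_fields], as.numeric))
    }
    out <- tibble::as_tibble(df)
    attr(out, "protocol") <- proto
    attr(out, "construct") <- meta$construct
    class(out) <- c("force_ramp_trace", class(out))
    out
  } else if (meta$kind == "force_clamp") {
    need <- c("time", "extension")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      abort(paste("Clamp trace missing column(s):", paste(miss, collapse = ", ")),
            class = "tweezfold_format_error")
    }
    .validate_times(df$time, n_header)
    sr <- as.numeric(meta$sample_rate)
    if (is.finite(sr)) .validate_spacing(df, sr, n_header)
    if ("force" %in% names(df)) {
      drift <- diff(range(df$force))
      if (drift > 0.1) {
        abort(sprintf(
          "Setpoint force drifts by %.3f pN (> 0.1 pN): not a constant-force trace.",
          drift), class = "tweezfold_validation_error")
      }
    }
    out <- tibble::as_tibble(df)
    attr(out, "setpoint_force") <- as.numeric(meta$setpoint_force)
    attr(out, "sample_rate") <- sr
    attr(out, "construct") <- meta$construct
    class(out) <- c("force_clamp_trace", class(out))
    out
  } else {
    abort(sprintf("Unknown trace kind '%s'.", meta$kind),
          class = "tweezfold_format_error")
  }
}

#' Write titration species counts
#'
#' @param counts A `species_counts` tibble.
#' @param path Output path (conventionally `*.counts.tsv`).
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  .counts_matrix(counts) # schema check
  readr::write_tsv(as.data.frame(counts), path)
  invisible(path)
}

#' Read titration species counts
#'
#' @param path Path to a `.counts.tsv` file.
#' @return A `species_counts` tibble.
#' @export
read_counts <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  .counts_matrix(df)
  out <- tibble::as_tibble(df)
  class(out) <- c("species_counts", class(out))
  out
}

# required columns for known result tables
.result_schemas <- list(
  rips = c("cycle_id", "direction", "rupture_force", "delta_x", "delta_lc",
           "reversible", "loading_rate"),
  kinetics = c("model", "role", "tau0", "dx_ddagger"),
  energies = c("domain", "construct", "condition", "dG_eq"),
  counts = c("conc_nM", "n_A0B0", "n_A1B0", "n_A0B1", "n_A1B1")
)

#' Write result tables with a digest manifest
#'
#' Writes each table of a named list as a TSV file under `path` with
#' deterministic column order and formatting, and a `manifest.json` listing
#' every file with its MD5 content digest. Tables whose names match a known
#' result schema (`rips`, `kinetics`, `energies`, `counts`) are checked for
#' their required columns first.
#'
#' @param tables Named list of data frames.
#' @param path Output directory (created if needed).
#' @return A tibble manifest (`table`, `file`, `md5`, `n_rows`), invisibly.
#' @export
write_results <- function(tables, path) {
  stopifnot(is.list(tables))
  if (length(tables) > 0 && is.null(names(tables))) {
    abort("`tables` must be a named list.", class = "tweezfold_invalid_input")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) {
    abort(sprintf("Cannot create output directory %s.", path),
          class = "tweezfold_io_error")
  }
  rows <- lapply(names(tables), function(nm) {
    df <- tables[[nm]]
    schema <- .result_schemas[[nm]]
    if (!is.null(schema)) {
      miss <- setdiff(schema, names(df))
      if (length(miss)) {
        abort(sprintf("Table '%s' is missing required field(s): %s.",
                      nm, paste(miss, collapse = ", ")),
              class = "tweezfold_schema_error")
      }
    }
    file <- file.path(path, paste0(nm, ".tsv"))
    df <- as.data.frame(df)[, sort(names(df)), drop = FALSE]
    readr::write_tsv(df, file)
    tibble::tibble(table = nm, file = basename(file),
                   md5 = unname(tools::md5sum(file)), n_rows = nrow(df))
  })
  manifest <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(table = character(), file = character(),
                   md5 = character(), n_rows = integer())
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
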