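# Delimited-file interchange.  A single CSV dialect is used everywhere:
# comment lines starting with '#' carry provenance (package version and the
# parameters of the run), then a header row whose column names carry the
# units, then the data.  Known schemas:
#   t_min,X_mm                            -> front trace
#   t_min,gap_mm                          -> gap trace
#   thickness_mm,t_star_s[,t_star_h][,converged] -> breakthrough curve
#   thickness_mm,replicate,t_obs_s        -> synthetic breakthrough table

trace_schemas <- list(
  front_trace        = c("t_min", "X_mm"),
  gap_trace          = c("t_min", "gap_mm"),
  breakthrough_curve = c("thickness_mm", "t_star_s"),
  breakthrough_obs   = c("thickness_mm", "replicate", "t_obs_s")
)

#' Read a trace or breakthrough table from CSV
#'
#' The schema is auto-detected from the header row; units are taken from the
#' column names.  Lines starting with `#` are provenance comments and are
#' skipped.  Malformed (non-numeric) rows are reported with their line
#' numbers; an empty data section yields an empty object with a warning.
#'
#' @param path path to a CSV file with a header row.
#' @return A [front_trace()], [gap_trace()], `"breakthrough_curve"` data
#'   frame, or a synthetic breakthrough observation table, according to the
#'   header.
#' @seealso [write_trace()]
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) {
    stop_bad(sprintf("file not found: %s", path), "delamsim_io")
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  if (!length(body)) {
    stop_bad("no header row found", "delamsim_io")
  }
  header <- strsplit(trimws(body[1]), ",")[[1]]
  schema <- NULL
  for (nm in names(trace_schemas)) {
    if (all(trace_schemas[[nm]] %in% header)) {
      schema <- nm
      break
    }
  }
  if (is.null(schema)) {
    stop_bad(sprintf(
      "unrecognized header '%s'; expected one of: %s",
      paste(header, collapse = ","),
      paste(vapply(trace_schemas, paste, "", collapse = ","), collapse = " | ")),
      "delamsim_io")
  }
  df <- read.csv(text = body, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning(sprintf("'%s': empty data section", path), call. = FALSE)
  }
  num_cols <- setdiff(names(df), "converged")
  for (cn in intersect(num_cols, header)) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]))
    if (length(bad)) {
      src_lines <- which(keep)[bad + 1L]   # +1 for header
      stop_bad(sprintf("malformed rows in '%s' (column %s): file line(s) %s",
                       path, cn, paste(src_lines, collapse = ", ")),
               "delamsim_io")
    }
    df[[cn]] <- v
  }
  switch(schema,
    front_trace = front_trace(df$t_min, df$X_mm),
    gap_trace = gap_trace(df$t_min, df$gap_mm),
    breakthrough_curve = {
      if (is.null(df$converged)) df$converged <- TRUE
      if (is.null(df$t_star_h)) df$t_star_h <- df$t_star_s / 3600
      df <- df[c("thickness_mm", "t_star_s", "t_star_h", "converged")]
      class(df) <- c("breakthrough_curve", "data.frame")
      df
    },
    breakthrough_obs = df)
}

#' Write a trace or breakthrough table to CSV
#'
#' Writes the standard header-row CSV preceded by provenance comment lines
#' (package version plus any supplied parameters).  Outputs are byte-identical
#' across runs for identical inputs — no timestamps are written.
#'
#' @param x a trace or breakthrough table.
#' @param path output path.
#' @param provenance named list or character vector recorded as `# key: value`
#'   comment lines.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# delamsim %s", as.character(packageVersion("delamsim"))),
             con)
  if (!is.null(provenance)) {
    writeLines(sprintf("# %s: %s", names(provenance),
                       vapply(provenance, function(v) paste(format(v), collapse = " "), "")),
               con)
  }
  write.csv(as.data.frame(x), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`), decided by extension.  If
#' `allowed` is given, unknown keys are rejected by name.
#'
#' @param path configuration file.
#' @param allowed optional character vector of permitted keys.
#' @return Named list of configuration values.
#' @export
read_config <- function(path, allowed = NULL) {
  if (!file.exists(path)) {
    stop_bad(sprintf("config file not found: %s", path), "delamsim_io")
  }
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop_bad(sprintf("unsupported config extension '%s' (use yaml or json)", ext),
             "delamsim_io"))
  if (!is.list(cfg)) {
    stop_bad("config must be a mapping of keys to values", "delamsim_io")
  }
  if (!is.null(allowed)) {
    unknown <- setdiff(names(cfg), allowed)
    if (length(unknown)) {
      stop_bad(sprintf("unknown config key(s): %s (allowed: %s)",
                       paste(unknown, collapse = ", "),
                       paste(allowed, collapse = ", ")),
               "delamsim_io")
    }
  }
  cfg
}
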