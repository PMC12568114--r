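#' Read and write session tables
#'
#' Session tables travel as UTF-8 comma-separated text with a documented
#' header: `session_id,user_id,sport,timestamp,heart_rate,speed,altitude,
#' latitude,longitude`, timestamps in ISO-8601 UTC. For synthetic cohorts the
#' `planted_duplicate` provenance flags are written to a sidecar file
#' (`<path>.provenance.csv`) so the main file matches the shape of real
#' wearable logs.
#'
#' @param table A session table.
#' @param path Path of the CSV file to write / read.
#' @return `write_sessions()` returns `path` invisibly; `read_sessions()`
#'   returns a session table tibble (with `planted_duplicate` re-attached when
#'   a sidecar file is present).
#' @export
write_sessions <- function(table, path) {
  assert_session_table(table)
  main <- table |>
    select(all_of(SESSION_COLUMNS)) |>
    mutate(timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  readr::write_csv(main, path)
  if ("planted_duplicate" %in% names(table)) {
    prov <- table |>
      distinct(.data$session_id, .data$planted_duplicate)
    readr::write_csv(prov, paste0(path, ".provenance.csv"))
  }
  invisible(path)
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path) {
  table <- readr::read_csv(
    path,
    col_types = readr::cols(
      session_id = readr::col_character(),
      user_id = readr::col_character(),
      sport = readr::col_character(),
      timestamp = readr::col_datetime(format = "%Y-%m-%dT%H:%M:%SZ"),
      heart_rate = readr::col_double(),
      speed = readr::col_double(),
      altitude = readr::col_double(),
      latitude = readr::col_double(),
      longitude = readr::col_double()
    ),
    progress = FALSE
  )
  probs <- readr::problems(table)
  if (nrow(probs) > 0) {
    abort(
      sprintf("Unparseable rows in %s at lines: %s", path,
              paste(unique(probs$row), collapse = ", ")),
      class = "ddmr_parse_error"
    )
  }
  sidecar <- paste0(path, ".provenance.csv")
  if (file.exists(sidecar)) {
    prov <- readr::read_csv(sidecar, col_types = "cl", progress = FALSE)
    table <- left_join(table, prov, by = "session_id")
  }
  attr(table, "spec") <- NULL
  as_tibble(table)
}
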