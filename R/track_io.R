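#' Read a cell position table into a movie
#'
#' Parses delimited text (comma or tab, sniffed from the header line) in one
#' of two dialects and normalizes it into an [movie()] object:
#'
#' * `generic_csv`: columns `track_id`, `label`, `t`, `x`, `y` and optionally
#'   `z`; `t` is literal seconds.
#' * `surface_export`: columns `Position X`, `Position Y`, `Position Z`,
#'   `Time`, `TrackID` and a class column (`Class`, `Label` or `Category`),
#'   the layout produced by surface-tracking exports. `Time` is a frame
#'   index, multiplied by `frame_interval` to obtain seconds. Exports in the
#'   wild use both 0-based and 1-based frame numbering; the base is detected
#'   from the file (0 if any `Time` equals 0, else 1) so the first frame
#'   always maps to t = 0. This dialect is a best-effort reconstruction of a
#'   vendor format whose exact schema varies between software versions;
#'   check the parse report after reading.
#'
#' Rows with non-finite coordinates are dropped and counted; the count is
#' attached to the returned movie as attribute `"parse_report"` (a list with
#' `n_rows`, `n_dropped`).
#'
#' @param source path to a delimited text file, or a connection.
#' @param dialect `"generic_csv"` or `"surface_export"`.
#' @param frame_interval seconds between frames (default 45); used to convert
#'   `surface_export` frame indices to seconds and stored as movie metadata.
#' @param ... further arguments (`movie_id`, `group`, `field_size_x`, ...)
#'   passed to [movie()]. Field sizes default to the data's bounding box
#'   rounded up when not supplied.
#' @return an `ivm_movie` with attribute `"parse_report"`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "track_id,label,t,x,y,z",
#'   "a,t_cell_resident,0,0,0,0",
#'   "a,t_cell_resident,45,3,0,0",
#'   "b,tumor,0,30,30,0",
#'   "b,tumor,45,30,30,0"
#' ), f)
#' m <- read_positions(f, dialect = "generic_csv")
#' attr(m, "parse_report")
#' @export
read_positions <- function(source, dialect = c("generic_csv", "surface_export"),
                           frame_interval = 45, ...) {
  dialect <- match.arg(dialect)
  lines <- readLines(source, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop_format("empty file: no header row found.")
  sep <- if (lengths(regmatches(lines[1], gregexpr("\t", lines[1]))) > 0) "\t" else ","
  raw <- utils::read.table(text = lines, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", "NaN", ""))
  if (nrow(raw) == 0) stop_format("empty file: header but no data rows.")

  if (dialect == "generic_csv") {
    needed <- c("track_id", "label", "t", "x", "y")
    miss <- setdiff(needed, names(raw))
    if (length(miss) > 0) {
      stop_format(sprintf("missing mandatory column(s): %s",
                          paste(miss, collapse = ", ")))
    }
    has_z <- "z" %in% names(raw)
    pos <- tibble(
      track_id = as.character(raw$track_id),
      label = as.character(raw$label),
      t = as.numeric(raw$t),
      x = as.numeric(raw$x),
      y = as.numeric(raw$y)
    )
    if (has_z) pos$z <- as.numeric(raw$z)
  } else {
    needed <- c("Position X", "Position Y", "Position Z", "Time", "TrackID")
    miss <- setdiff(needed, names(raw))
    if (length(miss) > 0) {
      stop_format(sprintf("missing mandatory column(s): %s",
                          paste(miss, collapse = ", ")))
    }
    class_col <- intersect(c("Class", "Label", "Category"), names(raw))
    if (length(class_col) == 0) {
      stop_format("missing mandatory column(s): Class (or Label/Category)")
    }
    frame_idx <- as.numeric(raw$Time)
    base <- if (any(frame_idx == 0, na.rm = TRUE)) 0 else 1
    pos <- tibble(
      track_id = as.character(raw$TrackID),
      label = normalize_class_label(raw[[class_col[1]]]),
      t = (frame_idx - base) * frame_interval,
      x = as.numeric(raw$`Position X`),
      y = as.numeric(raw$`Position Y`),
      z = as.numeric(raw$`Position Z`)
    )
  }

  coord_cols <- intersect(c("t", "x", "y", "z"), names(pos))
  ok <- Reduce(`&`, lapply(pos[coord_cols], is.finite))
  n_dropped <- sum(!ok)
  pos <- pos[ok, , drop = FALSE]
  if (nrow(pos) == 0) stop_format("no rows with finite coordinates remain.")

  dots <- list(...)
  if (is.null(dots$field_size_x)) dots$field_size_x <- max(ceiling(max(pos$x)), 1)
  if (is.null(dots$field_size_y)) dots$field_size_y <- max(ceiling(max(pos$y)), 1)
  m <- do.call(movie, c(list(positions = pos, frame_interval = frame_interval), dots))
  attr(m, "parse_report") <- list(n_rows = nrow(raw), n_dropped = n_dropped)
  m
}

# map free-text class names from exports onto the internal label enum
normalize_class_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("t_cell_resident", "tcell_resident", "resident",
               "t cell resident", "tcell")] <- "t_cell_resident"
  out[x %in% c("t_cell_peripheral", "tcell_peripheral", "peripheral",
               "recruited", "t cell peripheral")] <- "t_cell_peripheral"
  out[x %in% c("tumor", "tumour", "target")] <- "tumor"
  if (anyNA(out)) {
    stop_data(sprintf("unrecognized cell class value(s): %s",
                      paste(unique(x[is.na(out)]), collapse = ", ")))
  }
  out
}

#' Write a metrics table to delimited text
#'
#' Writes one `track` row per analyzed track followed by one `summary` row
#' per movie and per metric, in a single tab-delimited file distinguished by
#' a `row_type` column. Numeric values are written with 6 significant
#' digits. The companion [read_metrics()] round-trips the file.
#'
#' @param table an `ivm_metrics_table` from [summarize_movies()].
#' @param sink file path or writable connection.
#' @return `sink`, invisibly.
#' @export
write_metrics <- function(table, sink) {
  if (!inherits(table, "ivm_metrics_table")) {
    stop_usage("`table` must be an ivm_metrics_table (see summarize_movies()).")
  }
  if (nrow(table$tracks) == 0) stop_usage("empty metrics table.")
  tr <- table$tracks
  su <- table$movie_summary
  cols <- c("row_type", "movie_id", "group", "timepoint_h", "track_id",
            names(tr)[!names(tr) %in% c("movie_id", "group", "timepoint_h", "track_id")],
            "metric", "mean", "sem", "n_agg")
  t_rows <- tr
  t_rows$row_type <- "track"
  t_rows$metric <- NA_character_
  t_rows$mean <- NA_real_
  t_rows$sem <- NA_real_
  t_rows$n_agg <- NA_real_
  s_rows <- tibble(
    row_type = "summary", movie_id = su$movie_id, group = su$group,
    timepoint_h = su$timepoint_h, track_id = NA_character_,
    metric = su$metric, mean = su$mean, sem = su$sem, n_agg = su$n
  )
  for (cc in setdiff(cols, names(s_rows))) s_rows[[cc]] <- NA
  out <- rbind(as.data.frame(t_rows[cols]), as.data.frame(s_rows[cols]))
  num <- vapply(out, is.numeric, logical(1))
  for (cc in names(out)[num]) out[[cc]] <- fmt_num(out[[cc]])
  utils::write.table(out, sink, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(sink)
}

#' Read back a metrics table written by [write_metrics()]
#'
#' @param source file path or connection.
#' @return an `ivm_metrics_table` with `tracks` and `movie_summary` tibbles
#'   (group-level aggregates are not serialized and are absent).
#' @export
read_metrics <- function(source) {
  raw <- utils::read.table(source, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA")
  if (!"row_type" %in% names(raw)) stop_format("missing mandatory column(s): row_type")
  tr <- raw[raw$row_type == "track", , drop = FALSE]
  su <- raw[raw$row_type == "summary", , drop = FALSE]
  tracks <- as_tibble(tr[setdiff(names(tr), c("row_type", "metric", "mean", "sem", "n_agg"))])
  summary <- tibble(
    movie_id = as.character(su$movie_id), group = as.character(su$group),
    timepoint_h = as.numeric(su$timepoint_h), metric = as.character(su$metric),
    mean = as.numeric(su$mean), sem = as.numeric(su$sem), n = as.numeric(su$n_agg)
  )
  structure(list(tracks = tracks, movie_summary = summary,
                 group_summary = NULL, excluded = NULL),
            class = "ivm_metrics_table")
}
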