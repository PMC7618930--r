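#' Default column mapping for trajectory CSV files
#'
#' Maps the package's logical column roles to names in a delimited file.
#' Override individual entries to adapt to other tracker exports.
#'
#' @param track_id,frame,x,y,label Column names in the file.
#' @return Named character vector of column names.
#' @export
default_column_map <- function(track_id = "track_id", frame = "frame",
                               x = "x", y = "y", label = "label") {
  c(track_id = track_id, frame = frame, x = x, y = y, label = label)
}

#' Read trajectories from a delimited text file
#'
#' Reads a comma-delimited file with a header row and returns one
#' [trajectory()] per distinct track id, points sorted by frame. The label
#' column is optional; when present it must contain only the codes of
#' [label_codes()] (0/1) or the names `not_moving`/`moving`.
#'
#' @param path Path to a CSV file.
#' @param column_map Named character vector mapping roles
#'   (`track_id`, `frame`, `x`, `y`, `label`) to file column names;
#'   see [default_column_map()].
#' @return List of `trajectory` objects.
#' @export
read_trajectories <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  cm <- default_column_map()
  cm[names(column_map)] <- column_map
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  for (role in c("track_id", "frame", "x", "y")) {
    if (!cm[[role]] %in% names(df))
      stop(sprintf("required column '%s' (role %s) not found in %s",
                   cm[[role]], role, path))
  }
  if (nrow(df) == 0L) return(list())

  parse_num <- function(col, what) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric %s value in column '%s' at data row %d",
                   what, col, bad[1L]))
    v
  }
  ids <- df[[cm[["track_id"]]]]
  frame <- parse_num(cm[["frame"]], "frame")
  xs <- parse_num(cm[["x"]], "coordinate")
  ys <- parse_num(cm[["y"]], "coordinate")

  has_label <- cm[["label"]] %in% names(df)
  labels <- NULL
  if (has_label) {
    raw <- df[[cm[["label"]]]]
    raw[is.na(raw)] <- ""
    lv <- rep(NA_integer_, length(raw))
    lv[raw %in% c("0", "not_moving")] <- 0L
    lv[raw %in% c("1", "moving")] <- 1L
    bad <- which(is.na(lv) & raw != "")  # empty cells mean "unlabelled"
    if (length(bad))
      stop(sprintf("invalid label '%s' at data row %d: expected 0/1 or not_moving/moving",
                   raw[bad[1L]], bad[1L]))
    labels <- lv
  }

  out <- list()
  for (id in unique(ids)) {
    sel <- which(ids == id)
    if (anyDuplicated(frame[sel]))
      stop(sprintf("track '%s': duplicate frame index %d",
                   id, frame[sel][duplicated(frame[sel])][1L]))
    ord <- sel[order(frame[sel])]
    lab <- if (has_label) labels[ord] else NULL
    if (!is.null(lab) && all(is.na(lab))) lab <- NULL  # track written unlabelled
    if (!is.null(lab) && any(is.na(lab)))
      stop(sprintf("track '%s': partially labelled (some label cells empty)", id))
    out[[length(out) + 1L]] <- trajectory(
      track_id = id,
      frames = frame[ord],
      coords = cbind(x = xs[ord], y = ys[ord]),
      labels = lab
    )
  }
  out
}

#' Write trajectories to a delimited text file
#'
#' Writes the inverse of [read_trajectories()]: a header row plus one row per
#' point, coordinates serialized with 17 significant digits so that a
#' read-after-write round trip reproduces every double exactly.
#'
#' @param trajs List of [trajectory()] objects (may be empty).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  any_labels <- any(vapply(trajs, function(t) !is.null(t$labels), logical(1L)))
  header <- c("track_id", "frame", "x", "y", if (any_labels) "label")
  lines <- paste(header, collapse = ",")
  for (tr in trajs) {
    L <- trajectory_length(tr)
    row <- paste(rep(tr$track_id, L),
                 tr$frames,
                 sprintf("%.17g", tr$coords[, 1L]),
                 sprintf("%.17g", tr$coords[, 2L]),
                 sep = ",")
    if (any_labels) {
      lab <- if (is.null(tr$labels)) rep("", L) else as.character(tr$labels)
      row <- paste(row, lab, sep = ",")
    }
    lines <- c(lines, row)
  }
  con <- file(path, open = "wb")  # fixed newline convention => byte-stable output
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
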