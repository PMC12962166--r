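#' Write a trajectory recording in the DeepLabCut CSV dialect
#'
#' Three header rows (scorer / bodyparts / coords) followed by one row per
#' frame with x, y, likelihood triplets per bodypart. The belt-speed channel
#' and metadata are not part of the dialect; write them with
#' [write_trial_metadata()].
#'
#' @param rec a [trajectory_recording()].
#' @param path output file.
#' @param scorer scorer label placed in the first header row.
#' @return \code{path}, invisibly.
#' @export
write_dlc_csv <- function(rec, path, scorer = "synthetic") {
  bp <- colnames(rec$x)
  header1 <- c("scorer", rep(scorer, 3 * length(bp)))
  header2 <- c("bodyparts", rep(bp, each = 3))
  header3 <- c("coords", rep(c("x", "y", "likelihood"), length(bp)))
  body <- matrix(NA_real_, rec$frames, 3 * length(bp))
  for (j in seq_along(bp)) {
    body[, 3 * j - 2] <- rec$x[, j]
    body[, 3 * j - 1] <- rec$y[, j]
    body[, 3 * j] <- rec$likelihood[, j]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(header1, collapse = ","),
               paste(header2, collapse = ","),
               paste(header3, collapse = ",")), con)
  write.table(cbind(seq_len(rec$frames) - 1L, format(body, digits = 10, trim = TRUE)),
              con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a DeepLabCut-dialect CSV into a trajectory recording
#'
#' @param path CSV produced by DeepLabCut or [write_dlc_csv()].
#' @param frame_rate frames per second of the recording.
#' @param belt_speed optional belt-speed series (cm/s).
#' @param metadata optional metadata list (e.g. from [read_trial_metadata()]).
#' @return a [trajectory_recording()].
#' @export
read_dlc_csv <- function(path, frame_rate, belt_speed = NULL, metadata = list()) {
  hdr <- readLines(path, n = 3)
  h2 <- strsplit(hdr[2], ",")[[1]][-1]
  h3 <- strsplit(hdr[3], ",")[[1]][-1]
  dat <- read.csv(path, skip = 3, header = FALSE)
  dat <- as.matrix(dat[, -1, drop = FALSE])
  bp <- unique(h2)
  pick <- function(coord) {
    m <- dat[, h3 == coord, drop = FALSE]
    colnames(m) <- h2[h3 == coord]
    m[, bp, drop = FALSE]
  }
  trajectory_recording(pick("x"), pick("y"), pick("likelihood"),
                       frame_rate = frame_rate, belt_speed = belt_speed,
                       metadata = metadata)
}

#' Write / read the tidy long trajectory CSV
#'
#' Long format: one row per (frame, bodypart) with x, y, likelihood, plus a
#' \code{belt_speed} column repeated within each frame when present.
#'
#' @param rec a [trajectory_recording()].
#' @param path CSV path.
#' @return \code{path} ([write_tidy_csv()]) or a [trajectory_recording()]
#'   ([read_tidy_csv()]).
#' @export
write_tidy_csv <- function(rec, path) {
  bp <- colnames(rec$x)
  long <- data.frame(
    frame = rep(seq_len(rec$frames), times = length(bp)),
    bodypart = rep(bp, each = rec$frames),
    x = as.vector(rec$x), y = as.vector(rec$y),
    likelihood = as.vector(rec$likelihood)
  )
  if (!is.null(rec$belt_speed)) long$belt_speed <- rep(rec$belt_speed, length(bp))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tidy_csv
#' @param frame_rate frames per second.
#' @param metadata optional metadata list.
#' @export
read_tidy_csv <- function(path, frame_rate, metadata = list()) {
  long <- read.csv(path)
  bp <- unique(long$bodypart)
  nfr <- max(long$frame)
  shape <- function(col) {
    m <- matrix(long[[col]], nrow = nfr, ncol = length(bp))
    colnames(m) <- bp
    m
  }
  belt <- if ("belt_speed" %in% names(long)) long$belt_speed[seq_len(nfr)] else NULL
  trajectory_recording(shape("x"), shape("y"), shape("likelihood"),
                       frame_rate = frame_rate, belt_speed = belt,
                       metadata = metadata)
}

#' Write / read a load-cell trial CSV
#'
#' Columns: \code{time_s, ch_RF, ch_LF, ch_RH, ch_LH} (grams).
#'
#' @param trial a load trial (see [generate_load_trial()]).
#' @param path CSV path.
#' @return \code{path} or a \code{"load_trial"} list.
#' @export
write_load_csv <- function(trial, path) {
  df <- data.frame(time_s = trial$time,
                   ch_RF = trial$forces[, "RF"], ch_LF = trial$forces[, "LF"],
                   ch_RH = trial$forces[, "RH"], ch_LH = trial$forces[, "LH"])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_load_csv
#' @param metadata metadata list (e.g. from [read_trial_metadata()]).
#' @export
read_load_csv <- function(path, metadata = list()) {
  df <- read.csv(path)
  forces <- as.matrix(df[, c("ch_RF", "ch_LF", "ch_RH", "ch_LH")])
  colnames(forces) <- c("RF", "LF", "RH", "LH")
  structure(list(time = df$time_s, forces = forces, metadata = metadata),
            class = "load_trial")
}

# ---- minimal flat TOML (no TOML package exists in the installed stack) ----

.toml_scalar <- function(v) {
  if (is.character(v)) sprintf('"%s"', v)
  else if (is.logical(v)) tolower(as.character(v))
  else format(v, digits = 15, scientific = FALSE, trim = TRUE)
}

#' Write / read trial metadata as a flat TOML sidecar
#'
#' Supports scalar keys and flat arrays of numbers/strings/booleans under
#' optional \code{[section]} headers — the subset this package emits.
#'
#' @param metadata named list (values: scalars or flat vectors; nested lists
#'   of scalars become sections).
#' @param path TOML path.
#' @return \code{path} or the metadata list.
#' @export
write_trial_metadata <- function(metadata, path) {
  lines <- character(0)
  emit <- function(key, v) {
    if (length(v) == 1) sprintf("%s = %s", key, .toml_scalar(v))
    else sprintf("%s = [%s]", key, paste(vapply(v, .toml_scalar, ""), collapse = ", "))
  }
  sections <- Filter(function(k) is.list(metadata[[k]]) && !is.data.frame(metadata[[k]]),
                     names(metadata))
  flat <- setdiff(names(metadata), sections)
  for (k in flat) {
    v <- metadata[[k]]
    if (is.data.frame(v)) next # data.frames are not representable; skip
    lines <- c(lines, emit(k, v))
  }
  for (s in sections) {
    lines <- c(lines, "", sprintf("[%s]", s))
    for (k in names(metadata[[s]])) lines <- c(lines, emit(k, metadata[[s]][[k]]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trial_metadata
#' @export
read_trial_metadata <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  target <- function(section, key, value) {
    if (is.null(section)) {
      out[[key]] <<- value
    } else {
      path <- c(strsplit(section, ".", fixed = TRUE)[[1]], key)
      for (d in seq_len(length(path) - 1)) {
        if (is.null(out[[path[seq_len(d)]]])) out[[path[seq_len(d)]]] <<- list()
      }
      out[[path]] <<- value
    }
  }
  parse_val <- function(s) {
    s <- trimws(s)
    if (startsWith(s, "[")) {
      inner <- trimws(sub("\\]$", "", sub("^\\[", "", s)))
      if (!nzchar(inner)) return(list())
      parts <- trimws(strsplit(inner, ",")[[1]])
      return(unlist(lapply(parts, parse_val)))
    }
    if (startsWith(s, '"')) return(gsub('^"|"$', "", s))
    if (s %in% c("true", "false")) return(s == "true")
    as.numeric(s)
  }
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
    } else {
      kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
      target(section, trimws(kv[1]), parse_val(kv[2]))
    }
  }
  out
}

#' Write ground truth to JSON
#'
#' @param truth ground-truth list from [generate_trajectory_trial()].
#' @param path JSON path.
#' @return \code{path}, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
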