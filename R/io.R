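#' Read pose captures from CSV or JSON
#'
#' The CSV dialect has one row per landmark with header
#' `subject_id,session,view,landmark,x,y,z,visibility`; the JSON dialect is
#' an array of capture objects
#' `{subject_id, session, view, image_size, landmarks: {label: [x,y,z,visibility]}}`.
#' Unknown extra CSV columns are ignored with a warning. Subject metadata
#' (sex, age, height, weight) travels separately; pass it as `metadata` to
#' attach it on ingest.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @param metadata Optional data frame with columns `subject_id` and any of
#'   `sex`, `age`, `height`, `weight`.
#' @return A [cohort()] whose captures satisfy all capture invariants; row
#'   order of the file is preserved in subject and capture order.
#' @export
read_captures <- function(path, format = c("auto", "csv", "json"), metadata = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) {
    stop_posturekit(sprintf("file not found: %s", path), "io_error")
  }
  caps <- if (format == "csv") read_captures_csv(path) else read_captures_json(path)
  captures_to_cohort(caps, metadata, provenance = sprintf("read from %s", basename(path)))
}

read_captures_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("subject_id", "session", "view", "landmark", "x", "y", "z", "visibility")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_posturekit(
      sprintf("CSV lacks required column(s): %s", paste(missing_cols, collapse = ", ")),
      "format_error"
    )
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning(sprintf("ignoring unknown column(s): %s", paste(extra, collapse = ", ")))
    df <- df[required]
  }
  for (col in c("x", "y", "z", "visibility")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      line <- which(is.na(v))[1] + 1L # + header line
      stop_posturekit(
        sprintf("non-numeric '%s' value at line %d of %s", col, line, basename(path)),
        "parse_error"
      )
    }
    df[[col]] <- v
  }
  if (nrow(df) == 0) {
    return(list())
  }
  key <- paste(df$subject_id, df$session, df$view, sep = "\r")
  caps <- list()
  for (k in unique(key)) { # preserves file order
    block <- df[key == k, , drop = FALSE]
    caps[[length(caps) + 1L]] <- pose_capture(
      subject_id = block$subject_id[1],
      session = block$session[1],
      view = block$view[1],
      landmarks = block[c("landmark", "x", "y", "z", "visibility")]
    )
  }
  caps
}

read_captures_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  lapply(raw, function(obj) {
    lmlist <- obj$landmarks
    lm <- data.frame(
      landmark = names(lmlist),
      x = vapply(lmlist, function(v) as.numeric(v[[1]]), 0),
      y = vapply(lmlist, function(v) as.numeric(v[[2]]), 0),
      z = vapply(lmlist, function(v) as.numeric(v[[3]]), 0),
      visibility = vapply(lmlist, function(v) as.numeric(v[[4]]), 0),
      stringsAsFactors = FALSE
    )
    pose_capture(
      subject_id = obj$subject_id,
      session = obj$session,
      view = obj$view,
      landmarks = lm,
      image_size = if (!is.null(obj$image_size)) unlist(obj$image_size)
    )
  })
}

captures_to_cohort <- function(caps, metadata = NULL, provenance = "read") {
  ids <- unique(vapply(caps, function(cp) cp$subject_id, ""))
  meta_row <- function(id) {
    if (is.null(metadata)) {
      return(NULL)
    }
    m <- metadata[as.character(metadata$subject_id) == id, , drop = FALSE]
    if (nrow(m) == 0) NULL else m[1, ]
  }
  subjects <- lapply(ids, function(id) {
    m <- meta_row(id)
    getm <- function(col, default) {
      if (!is.null(m) && col %in% names(m)) m[[col]] else default
    }
    subject_record(
      subject_id = id,
      sex = getm("sex", NA_character_),
      age = getm("age", NA_real_),
      height = getm("height", NA_real_),
      weight = getm("weight", NA_real_),
      captures = Filter(function(cp) cp$subject_id == id, caps)
    )
  })
  cohort(subjects, provenance = provenance)
}

#' Write pose captures to CSV or JSON
#'
#' Writes the dialects read by [read_captures()], with deterministic field
#' and landmark ordering and full double precision, so that
#' `read_captures(write_captures(x))` reproduces coordinates exactly.
#'
#' @param x A [cohort()] or list of [pose_capture()] objects.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_captures <- function(x, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  caps <- if (inherits(x, "posture_cohort")) {
    unlist(lapply(x$subjects, function(s) s$captures), recursive = FALSE)
  } else {
    x
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (format == "csv") {
    header <- "subject_id,session,view,landmark,x,y,z,visibility"
    rows <- unlist(lapply(caps, function(cp) {
      lm <- cp$landmarks
      sprintf(
        "%s,%d,%s,%s,%s,%s,%s,%s",
        cp$subject_id, cp$session, cp$view, lm$landmark,
        fmt_num(lm$x), fmt_num(lm$y), fmt_num(lm$z), fmt_num(lm$visibility)
      )
    }))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(header, rows), con)
  } else {
    objs <- lapply(caps, function(cp) {
      lm <- cp$landmarks
      lmlist <- lapply(seq_len(nrow(lm)), function(i) {
        c(lm$x[i], lm$y[i], lm$z[i], lm$visibility[i])
      })
      names(lmlist) <- lm$landmark
      out <- list(
        subject_id = jsonlite::unbox(cp$subject_id),
        session = jsonlite::unbox(cp$session),
        view = jsonlite::unbox(cp$view),
        landmarks = lmlist
      )
      if (!is.null(cp$image_size)) out$image_size <- cp$image_size
      out
    })
    jsonlite::write_json(objs, path, digits = I(17), auto_unbox = FALSE)
  }
  invisible(path)
}

fmt_num <- function(x) {
  vapply(x, function(v) sprintf("%.17g", v), "")
}

#' Write subject metadata to CSV
#'
#' @param x A [cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(x, path) {
  df <- cohort_metadata(x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Subject metadata of a cohort as a data frame
#'
#' @param x A [cohort()].
#' @return Data frame with one row per subject: `subject_id`, `sex`, `age`,
#'   `height`, `weight`.
#' @export
cohort_metadata <- function(x) {
  do.call(rbind, lapply(x$subjects, function(s) {
    data.frame(
      subject_id = s$subject_id, sex = s$sex, age = s$age,
      height = s$height, weight = s$weight, stringsAsFactors = FALSE
    )
  }))
}
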