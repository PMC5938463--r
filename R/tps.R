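#' Landmark configurations and TPS file I/O
#'
#' A landmark configuration holds one shell's 20 labelled two-dimensional
#' landmarks (apex, suture points, body-whorl extremes, aperture extremes and
#' auxiliary points) in millimetres, after application of the digitizer's
#' scale factor.
#'
#' @name tps-io
NULL

#' Labels of the 20-landmark shell scheme
#'
#' Fixed labelling used throughout the package: the apex (LM1), the
#' intersections of the sutures with the shell outline (LM2-LM7), the most
#' external right and left points of the body whorl (LM8-LM9), the highest,
#' right, left and lowest points of the aperture (LM10-LM13) and auxiliary
#' points LM14-LM20.
#'
#' @return Character vector of length 20.
#' @export
landmark_labels <- function() {
  c("apex",
    paste0("suture", 1:6),
    "body_whorl_right", "body_whorl_left",
    "aperture_top", "aperture_right", "aperture_left", "aperture_bottom",
    paste0("aux", 1:7))
}

#' Create a landmark configuration
#'
#' @param points numeric 20 x 2 matrix (or `n_landmarks` x 2) of coordinates.
#'   Interpreted as already scaled to mm unless `scale` differs from 1, in
#'   which case `points * scale` is stored.
#' @param specimen_id specimen identifier.
#' @param scale mm-per-unit factor applied to `points`.
#' @param image optional source image name.
#' @param extra named character vector of additional TPS keyword records to
#'   preserve on round-trip.
#' @param n_landmarks expected number of landmarks (`NA` to accept any).
#' @return Object of class `landmark_config`: a list with elements `points`
#'   (mm), `specimen_id`, `scale`, `image`, `extra`.
#' @export
landmark_config <- function(points, specimen_id = NA_character_, scale = 1,
                            image = NA_character_, extra = character(),
                            n_landmarks = 20L) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L)
    stop("landmark configurations are two-dimensional (k x 2 matrix)")
  if (!all(is.finite(points)))
    stop("all landmark coordinates must be finite")
  if (!is.na(n_landmarks) && nrow(points) != n_landmarks)
    stop(sprintf("expected %d landmarks, got %d", n_landmarks, nrow(points)))
  structure(
    list(points = points * scale, specimen_id = as.character(specimen_id),
         scale = as.numeric(scale), image = as.character(image),
         extra = extra),
    class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("<landmark_config> %s: %d landmarks, CS = %.4f mm\n",
              x$specimen_id, nrow(x$points), centroid_size(x)))
  invisible(x)
}

#' Read a TPS landmark file
#'
#' Parses the tpsDig dialect: each record starts with `LM=<k>`, followed by
#' `k` coordinate lines, followed by optional keyword lines (`ID=`, `IMAGE=`,
#' `SCALE=`, ...; case-insensitive). Coordinates are multiplied by the
#' record's `SCALE=` factor when present, so stored coordinates are in mm.
#' Unknown keywords are preserved and written back by [write_tps()]. Line
#' endings may be LF or CRLF.
#'
#' @param path path to the TPS file.
#' @param n_landmarks expected landmark count per record (default 20; set to
#'   `NA` to accept any count).
#' @return List of [landmark_config()] objects, in file order.
#' @export
read_tps <- function(path, n_landmarks = 20L) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^\\s*lm\\s*=", lines, ignore.case = TRUE)
  if (length(starts) == 0L) return(list())
  ends <- c(starts[-1L] - 1L, length(lines))
  configs <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    k <- suppressWarnings(as.integer(sub("^\\s*lm\\s*=\\s*", "", block[1L],
                                         ignore.case = TRUE)))
    if (is.na(k)) stop(sprintf("record %d: unreadable LM= count", r))
    body <- block[-1L]
    is_kw <- grepl("^\\s*[a-zA-Z_][a-zA-Z0-9_]*\\s*=", body)
    coord_lines <- body[!is_kw]
    if (length(coord_lines) != k)
      stop(sprintf("record %d: LM=%d but %d coordinate lines",
                   r, k, length(coord_lines)))
    coords <- t(vapply(strsplit(trimws(coord_lines), "\\s+"), function(f) {
      v <- suppressWarnings(as.numeric(f))
      if (length(v) != 2L || anyNA(v))
        stop(sprintf("record %d: malformed coordinate line", r))
      v
    }, numeric(2)))
    kw_lines <- body[is_kw]
    kw_names <- toupper(trimws(sub("=.*$", "", kw_lines)))
    kw_vals <- trimws(sub("^[^=]*=", "", kw_lines))
    names(kw_vals) <- kw_names
    scale <- if ("SCALE" %in% kw_names) as.numeric(kw_vals[["SCALE"]]) else 1
    id <- if ("ID" %in% kw_names) kw_vals[["ID"]] else sprintf("specimen_%d", r)
    image <- if ("IMAGE" %in% kw_names) kw_vals[["IMAGE"]] else NA_character_
    extra <- kw_vals[!(kw_names %in% c("SCALE", "ID", "IMAGE"))]
    cfg <- tryCatch(
      landmark_config(coords, specimen_id = id, scale = scale, image = image,
                      extra = extra, n_landmarks = n_landmarks),
      error = function(e) stop(sprintf("record %d: %s", r, conditionMessage(e)),
                               call. = FALSE))
    configs[[r]] <- cfg
  }
  configs
}

#' Write landmark configurations to a TPS file
#'
#' Inverse of [read_tps()]: coordinates are written in the original digitizer
#' units (`points / scale`) together with the `SCALE=` record, so a
#' read-write round trip reproduces the stored mm coordinates to 6 decimals.
#'
#' @param configs list of [landmark_config()] objects (may be empty).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  stopifnot(is.list(configs))
  out <- character(0)
  for (cfg in configs) {
    raw <- cfg$points / cfg$scale
    rec <- c(sprintf("LM=%d", nrow(raw)),
             sprintf("%.6f %.6f", raw[, 1L], raw[, 2L]))
    if (!is.na(cfg$image)) rec <- c(rec, paste0("IMAGE=", cfg$image))
    rec <- c(rec, paste0("ID=", cfg$specimen_id))
    if (length(cfg$extra))
      rec <- c(rec, paste0(names(cfg$extra), "=", unname(cfg$extra)))
    if (cfg$scale != 1) rec <- c(rec, sprintf("SCALE=%g", cfg$scale))
    out <- c(out, rec)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

# Stack a list of landmark_config objects into a k x 2 x n array.
config_array <- function(configs) {
  stopifnot(length(configs) >= 1L)
  ks <- vapply(configs, function(c) nrow(c$points), integer(1))
  if (length(unique(ks)) != 1L)
    stop("all configurations must have the same landmark count")
  arr <- array(NA_real_, dim = c(ks[1L], 2L, length(configs)),
               dimnames = list(NULL, c("x", "y"),
                               vapply(configs, `[[`, "", "specimen_id")))
  for (i in seq_along(configs)) arr[, , i] <- configs[[i]]$points
  arr
}
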