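#' Landmark configuration
#'
#' A `landmark_set` holds one specimen's 2-D landmark configuration as
#' digitized from an image, together with its identifier and a flag recording
#' whether the configuration has been reflected (e.g. a left wing flipped to
#' match right wings).
#'
#' @param specimen_id Character scalar, unique within a file.
#' @param coords Numeric matrix with two columns (x, y), one row per landmark.
#' @param flipped Logical; has the configuration been reflected?
#' @param scale Optional numeric scalar, units per pixel (from a TPS `SCALE=`
#'   line). `NA` when absent.
#'
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(specimen_id, coords, flipped = FALSE, scale = NA_real_) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L)
    stop("coords must have two columns (x, y)")
  if (!all(is.finite(coords)))
    stop("landmark coordinates must all be finite for specimen ", specimen_id)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  structure(
    list(specimen_id = as.character(specimen_id), coords = coords,
         n_landmarks = nrow(coords), flipped = isTRUE(flipped),
         scale = as.numeric(scale)),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %s: %d landmarks%s%s\n", x$specimen_id,
              x$n_landmarks, if (x$flipped) " (flipped)" else "",
              if (!is.na(x$scale)) sprintf(", scale=%g", x$scale) else ""))
  invisible(x)
}

#' Read landmark configurations from a TPS file
#'
#' Parses the plain-text TPS format written by common digitizing software:
#' records start with `LM=<n>`, followed by `n` lines of `x y` coordinates and
#' optional `ID=`, `IMAGE=`, `SCALE=` lines. Keys are matched
#' case-insensitively and unknown keys are ignored, since digitizer output
#' varies. Coordinates are treated as Cartesian with y increasing upward;
#' set `flip_y = TRUE` for files using the image convention (y downward).
#'
#' @param path Path to a TPS file.
#' @param apply_scale If `TRUE`, multiply coordinates by the record's
#'   `SCALE=` value when present. Default `FALSE`: shape analysis is
#'   scale-invariant after Procrustes superimposition, so raw digitized units
#'   are kept unless physical units are explicitly requested.
#' @param flip_y If `TRUE`, negate y coordinates (image convention import).
#'
#' @return A list of [landmark_set] objects (empty list for an empty file).
#' @export
read_tps <- function(path, apply_scale = FALSE, flip_y = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sets <- list()
  i <- 1L
  rec <- 0L
  while (i <= length(lines)) {
    m <- regmatches(lines[i], regexec("^[Ll][Mm]=([0-9]+)$", lines[i]))[[1]]
    if (length(m) == 0L)
      stop(sprintf("TPS parse error before record %d: expected LM= line, got '%s'",
                   rec + 1L, lines[i]))
    rec <- rec + 1L
    n_lm <- as.integer(m[2])
    if (i + n_lm > length(lines))
      stop(sprintf("TPS parse error in record %d: LM=%d but only %d lines remain",
                   rec, n_lm, length(lines) - i))
    coord_lines <- lines[seq.int(i + 1L, length.out = n_lm)]
    xy <- lapply(seq_along(coord_lines), function(k) {
      parts <- strsplit(coord_lines[k], "[[:space:]]+")[[1]]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) != 2L || anyNA(vals))
        stop(sprintf("TPS parse error in record %d: non-numeric coordinate line '%s'",
                     rec, coord_lines[k]))
      vals
    })
    coords <- do.call(rbind, xy)
    i <- i + 1L + n_lm
    id <- sprintf("record_%d", rec)
    scale <- NA_real_
    # optional key lines until the next LM=
    while (i <= length(lines) && !grepl("^[Ll][Mm]=", lines[i])) {
      kv <- regmatches(lines[i], regexec("^([A-Za-z_]+)=(.*)$", lines[i]))[[1]]
      if (length(kv) == 0L)
        stop(sprintf("TPS parse error in record %d: unexpected line '%s'", rec, lines[i]))
      key <- toupper(kv[2])
      if (key == "ID") id <- trimws(kv[3])
      else if (key == "SCALE") scale <- as.numeric(kv[3])
      # IMAGE= and any other keys are ignored
      i <- i + 1L
    }
    if (flip_y) coords[, 2] <- -coords[, 2]
    if (apply_scale && !is.na(scale)) coords <- coords * scale
    sets[[rec]] <- landmark_set(id, coords, scale = scale)
  }
  ids <- vapply(sets, `[[`, character(1), "specimen_id")
  if (anyDuplicated(ids))
    warning("duplicate specimen ids in TPS file: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets
}

#' Write landmark configurations to a TPS file
#'
#' Inverse of [read_tps()]: the written file parses back to identical
#' coordinates (at printed precision, 15 significant digits).
#'
#' @param sets List of [landmark_set] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(sets, path) {
  lines <- unlist(lapply(sets, function(s) {
    stopifnot(inherits(s, "landmark_set"))
    c(sprintf("LM=%d", s$n_landmarks),
      apply(s$coords, 1, function(r)
        paste(formatC(r, format = "g", digits = 15), collapse = " ")),
      sprintf("ID=%s", s$specimen_id),
      if (!is.na(s$scale)) sprintf("SCALE=%s", formatC(s$scale, format = "g", digits = 15)))
  }))
  if (is.null(lines)) lines <- character(0)
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write TPS file ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Read a specimen table
#'
#' Reads the per-specimen CSV used across the pipeline, with columns
#' `specimen_id`, `site`, `population_type` (allopatric/contact), `species`
#' (A/B/hybrid/unknown), `genotyped`, `distance_km`, `wing_length`.
#'
#' @param path CSV path.
#' @param sep Field delimiter (default comma).
#' @return A data.frame.
#' @export
read_specimens <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("specimen_id", "species", "distance_km")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("specimen table missing columns: ", paste(miss, collapse = ", "))
  if ("genotyped" %in% names(df)) df$genotyped <- as.logical(df$genotyped)
  if ("population_type" %in% names(df)) {
    contact <- df$population_type == "contact"
    if (any(contact & !is.finite(df$distance_km)))
      stop("distance_km must be defined for all contact-zone specimens")
  }
  df
}
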