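# Oriented point annotations. A pick set carries the annotated object name,
# user and session identifiers, positions in angstrom (corner-origin frame)
# and one 4x4 pose transform per pick; optional per-pick scores survive all
# round trips verbatim.

#' Construct a pick set
#'
#' @param object Pickable object name.
#' @param user,session User and session identifiers (no underscores; they
#'   delimit fields in on-disk names).
#' @param positions n x 3 numeric matrix, columns x, y, z in angstrom.
#' @param transforms List of n 4x4 pose transforms; `NULL` gives identity
#'   poses.
#' @param scores Optional numeric vector of length n.
#' @return Object of class `pick_set`.
#' @export
pick_set <- function(object, user, session, positions = matrix(numeric(), 0, 3),
                     transforms = NULL, scores = NULL) {
  positions <- matrix(as.numeric(positions), ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z")))
  n <- nrow(positions)
  for (id in c(user, session)) {
    if (grepl("_", id))
      tp_stop("user/session ids may not contain '_'", "tomopick_validation_error")
  }
  if (is.null(transforms)) transforms <- replicate(n, diag(4), simplify = FALSE)
  if (length(transforms) != n)
    tp_stop("need one transform per pick", "tomopick_validation_error")
  transforms <- lapply(transforms, validate_transform)
  if (any(!is.finite(positions)))
    tp_stop("pick positions must be finite", "tomopick_validation_error")
  if (!is.null(scores) && length(scores) != n)
    tp_stop("need one score per pick", "tomopick_validation_error")
  structure(list(object = object, user = user, session = session,
                 positions = positions, transforms = transforms,
                 scores = scores),
            class = "pick_set")
}

#' @export
print.pick_set <- function(x, ...) {
  cat(sprintf("<pick_set object=%s user=%s session=%s n=%d>\n",
              x$object, x$user, x$session, nrow(x$positions)))
  invisible(x)
}

#' @export
length.pick_set <- function(x) nrow(x$positions)

subset_picks <- function(ps, keep) {
  pick_set(ps$object, ps$user, ps$session,
           ps$positions[keep, , drop = FALSE],
           ps$transforms[keep],
           if (is.null(ps$scores)) NULL else ps$scores[keep])
}

#' Write a pick set to JSON
#'
#' Positions and transforms are serialized at full double precision so the
#' read-back equals the written values bit for bit.
#'
#' @param ps A `pick_set`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_picks <- function(ps, path) {
  writeBin(picks_to_json(ps), path)
  invisible(path)
}

# serialized by hand with %.17g so that doubles survive the round trip
# bit for bit (generic JSON writers stop at 15 significant digits)
picks_to_json <- function(ps) {
  num <- function(x) sprintf("%.17g", x)
  jstr <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  n <- nrow(ps$positions)
  points <- vapply(seq_len(n), function(i) {
    T <- unclass(ps$transforms[[i]])
    rows <- vapply(1:4, function(r)
      paste0("[", paste(num(T[r, ]), collapse = ","), "]"), character(1))
    paste0(
      '{"location":{"x":', num(ps$positions[i, 1]),
      ',"y":', num(ps$positions[i, 2]),
      ',"z":', num(ps$positions[i, 3]),
      '},"transformation":[', paste(rows, collapse = ","), "]",
      if (!is.null(ps$scores)) paste0(',"score":', num(ps$scores[i])) else "",
      "}")
  }, character(1))
  charToRaw(paste0(
    '{"pickable_object_name":', jstr(ps$object),
    ',"user_id":', jstr(ps$user),
    ',"session_id":', jstr(ps$session),
    ',"points":[', paste(points, collapse = ","), "]}"))
}

#' Read a pick set from JSON
#'
#' @param path Source file.
#' @return A `pick_set`; malformed documents or invalid pose matrices raise
#'   validation errors.
#' @export
read_picks <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    tp_stop(paste0("malformed pick JSON: ", conditionMessage(e)),
                            "tomopick_format_error"))
  json_to_picks(doc)
}

json_to_picks <- function(doc) {
  pts <- doc$points
  n <- length(pts)
  pos <- matrix(0, n, 3)
  trs <- vector("list", n)
  scores <- numeric(n)
  has_score <- FALSE
  for (i in seq_len(n)) {
    loc <- pts[[i]]$location
    pos[i, ] <- c(loc$x, loc$y, loc$z)
    tr <- pts[[i]]$transformation
    if (length(tr) != 4L || any(lengths(tr) != 4L))
      tp_stop("pick transformation must be a 4x4 matrix",
              "tomopick_validation_error")
    trs[[i]] <- do.call(rbind, lapply(tr, unlist))
    if (!is.null(pts[[i]]$score)) {
      has_score <- TRUE
      scores[i] <- pts[[i]]$score
    } else scores[i] <- NA_real_
  }
  pick_set(doc$pickable_object_name, doc$user_id, doc$session_id,
           pos, trs, if (has_score) scores else NULL)
}

# ---- external particle formats ----------------------------------------------

parse_star <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  i <- which(lines == "loop_")
  if (length(i) == 0)
    tp_stop("no loop_ block found in STAR file", "tomopick_format_error")
  i <- i[1] + 1L
  tags <- character()
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    tags <- c(tags, sub("\\s*#.*$", "", lines[i]))
    i <- i + 1L
  }
  rows <- list()
  while (i <= length(lines) && nzchar(lines[i]) && !startsWith(lines[i], "data_")) {
    rows[[length(rows) + 1L]] <- strsplit(lines[i], "\\s+")[[1]]
    i <- i + 1L
  }
  tab <- do.call(rbind, rows)
  colnames(tab) <- tags
  tab
}

#' Import picks from STAR, Dynamo table or CSV
#'
#' Coordinates are converted to angstrom in the corner-origin frame;
#' orientations are converted to pose matrices through the matrix
#' representation ([convert_orientation()]). STAR and Dynamo files commonly
#' store voxel coordinates, so those formats require an explicit `units`
#' flag (plus `spacing` for voxel units) rather than guessing.
#'
#' @param path Input file.
#' @param format `"star"`, `"dynamo"` or `"csv"` (default from extension).
#' @param units `"angstrom"` or `"voxel"`. Default `"angstrom"` for CSV;
#'   mandatory for STAR/Dynamo.
#' @param spacing Voxel spacing in angstrom; required when `units = "voxel"`.
#' @param object,user,session Attribution for the resulting pick set.
#' @return A `pick_set`.
#' @export
import_picks <- function(path, format = NULL, units = NULL, spacing = NULL,
                         object = "particle", user = "import", session = "0") {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, star = "star", tbl = "dynamo", csv = "csv",
                     tp_stop(paste0("unknown picks format: .", ext),
                             "tomopick_format_error"))
  }
  if (format %in% c("star", "dynamo") && is.null(units))
    tp_stop("coordinate units are ambiguous for this format; pass units = \"angstrom\" or \"voxel\"",
            "tomopick_value_error")
  if (is.null(units)) units <- "angstrom"
  if (units == "voxel" && (is.null(spacing) || spacing <= 0))
    tp_stop("voxel units require a positive `spacing`", "tomopick_value_error")
  scale <- if (units == "voxel") spacing else 1
  if (format == "csv") {
    tab <- utils::read.csv(path, check.names = FALSE)
    need <- c("x", "y", "z")
    if (!all(need %in% names(tab)))
      tp_stop(paste0("CSV is missing coordinate columns: ",
                     paste(setdiff(need, names(tab)), collapse = ", ")),
              "tomopick_format_error")
    pos <- as.matrix(tab[, need]) * scale
    trs <- NULL
    if (all(c("rot", "tilt", "psi") %in% names(tab))) {
      trs <- lapply(seq_len(nrow(tab)), function(i)
        pick_transform(matrix_from_euler(
          c(tab$rot[i], tab$tilt[i], tab$psi[i]), "relion")))
    }
    scores <- if ("score" %in% names(tab)) tab$score else NULL
    return(pick_set(object, user, session, pos, trs, scores))
  }
  if (format == "star") {
    tab <- parse_star(path)
    need <- c("_rlnCoordinateX", "_rlnCoordinateY", "_rlnCoordinateZ")
    if (!all(need %in% colnames(tab)))
      tp_stop(paste0("STAR file is missing coordinate columns: ",
                     paste(setdiff(need, colnames(tab)), collapse = ", ")),
              "tomopick_format_error")
    pos <- apply(tab[, need, drop = FALSE], 2, as.numeric)
    pos <- matrix(pos, ncol = 3) * scale
    atags <- c("_rlnAngleRot", "_rlnAngleTilt", "_rlnAnglePsi")
    trs <- NULL
    if (all(atags %in% colnames(tab))) {
      ang <- apply(tab[, atags, drop = FALSE], 2, as.numeric)
      ang <- matrix(ang, ncol = 3)
      trs <- lapply(seq_len(nrow(ang)), function(i)
        pick_transform(matrix_from_euler(ang[i, ], "relion")))
    }
    return(pick_set(object, user, session, pos, trs))
  }
  # dynamo: whitespace-separated 35-column table; coordinates in columns
  # 24:26, shifts in 4:6 (same units as coordinates), angles in 7:9
  tab <- as.matrix(utils::read.table(path))
  if (ncol(tab) < 26)
    tp_stop("Dynamo table needs at least 26 columns", "tomopick_format_error")
  pos <- (tab[, 24:26, drop = FALSE] + tab[, 4:6, drop = FALSE]) * scale
  trs <- lapply(seq_len(nrow(tab)), function(i)
    pick_transform(matrix_from_euler(tab[i, 7:9], "dynamo")))
  pick_set(object, user, session, pos, trs)
}

#' Export picks to STAR, Dynamo table or CSV
#'
#' Positions are written in the requested units (`spacing` required for
#' voxel units); shifts are folded into the coordinates and orientations are
#' exported through the matrix representation into each dialect's angles, in
#' degrees. Shifts exported by this package are always in angstrom.
#'
#' @param ps A `pick_set`.
#' @param path Destination file.
#' @param format `"star"`, `"dynamo"` or `"csv"`.
#' @param units `"angstrom"` (default) or `"voxel"`.
#' @param spacing Required for voxel units.
#' @return `path`, invisibly.
#' @export
export_picks <- function(ps, path, format = c("csv", "star", "dynamo"),
                         units = "angstrom", spacing = NULL) {
  format <- match.arg(format)
  if (units == "voxel" && (is.null(spacing) || spacing <= 0))
    tp_stop("voxel units require a positive `spacing`", "tomopick_value_error")
  scale <- if (units == "voxel") 1 / spacing else 1
  pos <- ps$positions * scale
  n <- nrow(pos)
  rots <- lapply(ps$transforms, function(T) unclass(T)[1:3, 1:3])
  if (format == "csv") {
    ang <- t(vapply(rots, euler_from_matrix, numeric(3), convention = "relion"))
    df <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                     rot = ang[, 1], tilt = ang[, 2], psi = ang[, 3])
    if (!is.null(ps$scores)) df$score <- ps$scores
    utils::write.csv(df, path, row.names = FALSE)
  } else if (format == "star") {
    ang <- t(vapply(rots, euler_from_matrix, numeric(3), convention = "relion"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("", "data_particles", "", "loop_",
                 "_rlnCoordinateX #1", "_rlnCoordinateY #2", "_rlnCoordinateZ #3",
                 "_rlnAngleRot #4", "_rlnAngleTilt #5", "_rlnAnglePsi #6"), con)
    writeLines(sprintf("%.6f\t%.6f\t%.6f\t%.6f\t%.6f\t%.6f",
                       pos[, 1], pos[, 2], pos[, 3],
                       ang[, 1], ang[, 2], ang[, 3]), con)
  } else {
    ang <- t(vapply(rots, euler_from_matrix, numeric(3), convention = "dynamo"))
    tab <- matrix(0, n, 35)
    tab[, 1] <- seq_len(n)
    tab[, 7:9] <- ang
    tab[, 24:26] <- pos
    utils::write.table(tab, path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
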