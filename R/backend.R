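# Pluggable storage backends. A backend is a set of closures implementing a
# uniform read/write/list/delete/exists contract over string keys ("a/b/c").
# Layer roots are resolved to backends through a scheme registry so remote
# stores (SSH, S3, ...) can be plugged in without touching the data model.

.backend_registry <- new.env(parent = emptyenv())

tp_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "tomopick_error")))
}

#' Local filesystem storage backend
#'
#' Implements the storage contract (`read`, `write`, `list`, `delete`,
#' `exists`, `size`) over a directory tree. Keys are `/`-separated paths
#' relative to `root`.
#'
#' @param root Directory that holds the store (created if absent).
#' @param read_only If `TRUE`, any write or delete raises an error. Used to
#'   enforce static-layer semantics.
#' @return An object of class `tomopick_backend`.
#' @export
local_backend <- function(root, read_only = FALSE) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  root <- normalizePath(root, mustWork = TRUE)
  full <- function(key) {
    if (grepl("\\.\\.", key)) tp_stop("key may not contain '..'", "tomopick_io_error")
    file.path(root, key)
  }
  guard <- function() {
    if (read_only)
      tp_stop(paste0("layer at ", root, " is static (read-only)"),
              "tomopick_readonly_error")
  }
  structure(list(
    root = root,
    read_only = read_only,
    read = function(key) {
      p <- full(key)
      if (!file.exists(p)) tp_stop(paste0("no such key: ", key), "tomopick_io_error")
      readBin(p, "raw", file.info(p)$size)
    },
    write = function(key, bytes) {
      guard()
      p <- full(key)
      dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
      writeBin(bytes, p)
      invisible(key)
    },
    list = function(prefix = "") {
      p <- if (nzchar(prefix)) full(prefix) else root
      if (!dir.exists(p)) return(character())
      fs <- list.files(p, recursive = TRUE, all.files = TRUE, no.. = TRUE)
      fs <- fs[!dir.exists(file.path(p, fs))]
      if (nzchar(prefix)) file.path(prefix, fs) else fs
    },
    exists = function(key) file.exists(full(key)),
    delete = function(key) {
      guard()
      unlink(full(key), recursive = TRUE)
      invisible(key)
    }
  ), class = "tomopick_backend")
}

#' Instrumented backend wrapper recording every key that is read
#'
#' Wraps an existing backend; reads are recorded in `$log$reads`. Used to
#' assert that partial region reads touch only the chunks that intersect the
#' requested region.
#'
#' @param backend A `tomopick_backend`.
#' @return A `tomopick_backend` with a `log` environment.
#' @export
counting_backend <- function(backend) {
  log <- new.env(parent = emptyenv())
  log$reads <- character()
  structure(list(
    root = backend$root,
    read_only = backend$read_only,
    read = function(key) {
      log$reads <- c(log$reads, key)
      backend$read(key)
    },
    write = backend$write,
    list = backend$list,
    exists = backend$exists,
    delete = backend$delete,
    log = log
  ), class = "tomopick_backend")
}

#' Register a storage backend factory for a URI scheme
#'
#' @param scheme URI scheme (e.g. `"s3"`); `"file"` and scheme-less paths are
#'   handled by the built-in local backend.
#' @param factory Function `(uri, read_only)` returning a `tomopick_backend`.
#' @export
register_storage_backend <- function(scheme, factory) {
  stopifnot(is.character(scheme), is.function(factory))
  assign(scheme, factory, envir = .backend_registry)
  invisible(scheme)
}

backend_for_uri <- function(uri, read_only = FALSE) {
  m <- regmatches(uri, regexec("^([a-zA-Z][a-zA-Z0-9+.-]*)://(.*)$", uri))[[1]]
  if (length(m) == 0) return(local_backend(uri, read_only = read_only))
  scheme <- m[2]
  if (scheme %in% c("file", "local"))
    return(local_backend(m[3], read_only = read_only))
  if (exists(scheme, envir = .backend_registry, inherits = FALSE))
    return(get(scheme, envir = .backend_registry)(uri, read_only))
  tp_stop(paste0("no storage backend registered for scheme '", scheme, "'"),
          "tomopick_io_error")
}
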