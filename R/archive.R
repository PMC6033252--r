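# Chunked, indexed key-value store for packages. A stored entry mirrors the
# files/chunks split of a GridFS-style blob store: a file document (length,
# chunk size, chunk count, checksum) plus ordered fixed-size chunks. Primary
# index on the HIMS id; secondary indexes on the patient search fields.
# Backends: in-memory (default, tests) and file-directory persistence, both
# behind the same contract.

DEFAULT_CHUNK_SIZE <- 255L * 1024L

#' Open an archive
#'
#' @param backend `"memory"` or `"file"`.
#' @param path Directory for the file backend (created if absent).
#' @param chunk_size Chunk size in bytes (default 255 KiB, the GridFS
#'   convention; chunking keeps any single stored document under the usual
#'   16 MB document-size limit).
#' @return A `roipack_archive` handle.
#' @export
archive_open <- function(backend = c("memory", "file"), path = NULL,
                         chunk_size = DEFAULT_CHUNK_SIZE) {
  backend <- match.arg(backend)
  stopifnot(chunk_size >= 1L)
  if (backend == "file") {
    if (is.null(path)) {
      rp_stop("roipack_format_error", "file backend needs a path")
    }
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
  }
  structure(
    list(
      backend = backend,
      path = path,
      chunk_size = as.integer(chunk_size),
      store = new.env(parent = emptyenv()),
      index = new.env(parent = emptyenv())
    ),
    class = "roipack_archive"
  )
}

#' @export
print.roipack_archive <- function(x, ...) {
  cat(sprintf("<roipack_archive> backend=%s, %d entr%s, chunk_size=%d\n",
              x$backend, length(archive_ids(x)),
              if (length(archive_ids(x)) == 1L) "y" else "ies",
              x$chunk_size))
  invisible(x)
}

archive_ids <- function(ar) {
  if (ar$backend == "memory") {
    sort(as.integer(ls(ar$store)))
  } else {
    dirs <- list.dirs(ar$path, recursive = FALSE, full.names = FALSE)
    sort(as.integer(dirs[grepl("^[0-9]+$", dirs)]))
  }
}

split_chunks <- function(blob, chunk_size) {
  len <- length(blob)
  n_chunks <- ceiling(len / chunk_size)
  if (n_chunks == 0L) {
    return(list())
  }
  lapply(seq_len(n_chunks), function(i) {
    from <- (i - 1L) * chunk_size + 1L
    blob[from:min(len, i * chunk_size)]
  })
}

entry_meta <- function(hims_id, patient, blob, chunk_size) {
  list(
    hims_id = as.integer(hims_id),
    patient = lapply(patient, as.character),
    length = length(blob),
    chunk_size = as.integer(chunk_size),
    n_chunks = as.integer(ceiling(length(blob) / chunk_size)),
    checksum = .adler32(blob)
  )
}

#' Store a package blob under a HIMS id
#'
#' Splits the blob into fixed-size chunks, records the file document
#' (length, chunk count, Adler-32 checksum), and updates the primary and
#' patient-field indexes.
#'
#' @param ar A [archive_open()] handle.
#' @param hims_id Unique integer key.
#' @param patient Named list with any of `name`, `surname`,
#'   `citizenship_id`, `study_date` (ISO-8601 string).
#' @param blob Raw vector.
#' @param overwrite Allow replacing an existing id.
#' @return The stored entry (invisibly): file document plus chunks.
#' @export
archive_put <- function(ar, hims_id, patient = list(), blob,
                        overwrite = FALSE) {
  stopifnot(inherits(ar, "roipack_archive"), is.raw(blob))
  hims_id <- as.integer(hims_id)
  key <- as.character(hims_id)
  exists_already <- !is.null(archive_meta(ar, hims_id))
  if (exists_already && !overwrite) {
    rp_stop("roipack_key_conflict",
            "HIMS id %d already stored (use overwrite = TRUE)", hims_id)
  }
  meta <- entry_meta(hims_id, patient, blob, ar$chunk_size)
  chunks <- split_chunks(blob, ar$chunk_size)
  if (ar$backend == "memory") {
    assign(key, list(meta = meta, chunks = chunks), envir = ar$store)
  } else {
    dir <- file.path(ar$path, key)
    unlink(dir, recursive = TRUE)
    dir.create(dir, recursive = TRUE)
    writeLines(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE)),
               file.path(dir, "meta.json"))
    for (i in seq_along(chunks)) {
      writeBin(chunks[[i]], file.path(dir, sprintf("chunk_%06d.bin", i)))
    }
  }
  update_indexes(ar, meta, remove = FALSE)
  invisible(structure(c(meta, list(chunks = chunks)),
                      class = "archive_entry"))
}

archive_meta <- function(ar, hims_id) {
  key <- as.character(as.integer(hims_id))
  if (ar$backend == "memory") {
    if (!exists(key, envir = ar$store, inherits = FALSE)) {
      return(NULL)
    }
    get(key, envir = ar$store, inherits = FALSE)$meta
  } else {
    f <- file.path(ar$path, key, "meta.json")
    if (!file.exists(f)) {
      return(NULL)
    }
    m <- jsonlite::fromJSON(paste(readLines(f, warn = FALSE), collapse = ""),
                            simplifyVector = FALSE)
    m$hims_id <- as.integer(m$hims_id)
    m$length <- as.integer(m$length)
    m$chunk_size <- as.integer(m$chunk_size)
    m$n_chunks <- as.integer(m$n_chunks)
    m$checksum <- as.numeric(m$checksum)
    m$patient <- lapply(m$patient, as.character)
    m
  }
}

archive_chunks <- function(ar, hims_id) {
  key <- as.character(as.integer(hims_id))
  if (ar$backend == "memory") {
    get(key, envir = ar$store, inherits = FALSE)$chunks
  } else {
    dir <- file.path(ar$path, key)
    files <- sort(list.files(dir, pattern = "^chunk_[0-9]+\\.bin$",
                             full.names = TRUE))
    lapply(files, function(f) readBin(f, "raw", n = file.size(f)))
  }
}

# secondary indexes: one environment per field mapping value -> integer ids
update_indexes <- function(ar, meta, remove = FALSE) {
  for (field in c("name", "surname", "citizenship_id", "study_date")) {
    v <- meta$patient[[field]]
    if (is.null(v) || !nzchar(v)) next
    if (is.null(ar$index[[field]])) {
      ar$index[[field]] <- new.env(parent = emptyenv())
    }
    idx <- ar$index[[field]]
    ids <- if (exists(v, envir = idx, inherits = FALSE)) {
      get(v, envir = idx, inherits = FALSE)
    } else {
      integer(0)
    }
    ids <- if (remove) setdiff(ids, meta$hims_id) else
      sort(unique(c(ids, meta$hims_id)))
    assign(v, ids, envir = idx)
  }
}

# rebuild indexes from stored metadata (file backend re-opened cold)
rebuild_indexes <- function(ar) {
  for (id in archive_ids(ar)) {
    update_indexes(ar, archive_meta(ar, id))
  }
  invisible(ar)
}

#' Retrieve a blob by HIMS id
#'
#' Reassembles the chunks in index order and verifies length and checksum.
#'
#' @param ar A `roipack_archive`.
#' @param hims_id Integer key.
#' @return Raw vector.
#' @export
archive_get <- function(ar, hims_id) {
  meta <- archive_meta(ar, hims_id)
  if (is.null(meta)) {
    rp_stop("roipack_not_found", "HIMS id %s not in archive",
            as.character(hims_id))
  }
  chunks <- archive_chunks(ar, hims_id)
  blob <- if (length(chunks) == 0L) raw(0L) else do.call(c, chunks)
  if (length(blob) != meta$length || .adler32(blob) != meta$checksum) {
    rp_stop("roipack_consistency_error",
            "stored chunks do not reassemble to the recorded blob")
  }
  blob
}

#' Direct search by primary key
#'
#' @param ar A `roipack_archive`.
#' @param hims_id Integer key.
#' @return An `archive_entry`: file document plus chunks.
#' @export
search_by_id <- function(ar, hims_id) {
  meta <- archive_meta(ar, hims_id)
  if (is.null(meta)) {
    rp_stop("roipack_not_found", "HIMS id %s not in archive",
            as.character(hims_id))
  }
  structure(c(meta, list(chunks = archive_chunks(ar, hims_id))),
            class = "archive_entry")
}

#' Criteria search over patient fields
#'
#' Conjunctive match over whichever criteria are provided; returns the
#' matching HIMS-id list in ascending order (the caller then fetches each
#' package by id - the two-step search flow). Dates are ISO-8601 strings
#' compared lexicographically over the half-open range
#' `[date_from, date_to)`.
#'
#' @param ar A `roipack_archive`.
#' @param name,surname,citizenship_id Exact-match criteria (optional).
#' @param date_from,date_to Half-open study-date range (optional; either
#'   bound may be given alone).
#' @param allow_scan Permit a criteria-less full listing.
#' @return Integer vector of HIMS ids, ascending.
#' @export
search_by_criteria <- function(ar, name = NULL, surname = NULL,
                               citizenship_id = NULL, date_from = NULL,
                               date_to = NULL, allow_scan = FALSE) {
  stopifnot(inherits(ar, "roipack_archive"))
  no_criteria <- is.null(name) && is.null(surname) &&
    is.null(citizenship_id) && is.null(date_from) && is.null(date_to)
  if (no_criteria) {
    if (!allow_scan) {
      rp_stop("roipack_empty_criteria",
              "no criteria given; pass allow_scan = TRUE for a full listing")
    }
    return(archive_ids(ar))
  }
  if (ar$backend == "file" && length(ls(ar$index)) == 0L) {
    rebuild_indexes(ar)
  }
  lookup <- function(field, value) {
    idx <- ar$index[[field]]
    if (is.null(idx) || !exists(value, envir = idx, inherits = FALSE)) {
      integer(0)
    } else {
      get(value, envir = idx, inherits = FALSE)
    }
  }
  cand <- NULL
  intersect_with <- function(cand, ids) {
    if (is.null(cand)) ids else intersect(cand, ids)
  }
  if (!is.null(name)) cand <- intersect_with(cand, lookup("name", name))
  if (!is.null(surname)) {
    cand <- intersect_with(cand, lookup("surname", surname))
  }
  if (!is.null(citizenship_id)) {
    cand <- intersect_with(cand, lookup("citizenship_id", citizenship_id))
  }
  if (!is.null(date_from) || !is.null(date_to)) {
    pool <- if (is.null(cand)) archive_ids(ar) else cand
    keep <- vapply(pool, function(id) {
      d <- archive_meta(ar, id)$patient[["study_date"]]
      if (is.null(d) || !nzchar(d)) {
        return(FALSE)
      }
      (is.null(date_from) || d >= date_from) &&
        (is.null(date_to) || d < date_to)
    }, logical(1))
    cand <- pool[keep]
  }
  sort(as.integer(cand))
}

#' @export
print.archive_entry <- function(x, ...) {
  cat(sprintf("<archive_entry> HIMSID=%d, %d bytes in %d chunk(s)\n",
              x$hims_id, x$length, x$n_chunks))
  invisible(x)
}
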