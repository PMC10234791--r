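#' Read a Webmorph TEM landmark file
#'
#' Parses the TEM dialect exported by Webmorph delineation: the first line is
#' the landmark count, followed by one whitespace-separated `x y` pair per
#' line. Any trailing block (Webmorph line-connectivity definitions) is
#' skipped without error. Point order is semantic — landmark *k* on one face
#' corresponds to landmark *k* on every other face — and is never permuted.
#'
#' @param file Path to a `.tem` file, or a character string containing the
#'   file's text (recognised by embedded newlines or length > 1).
#' @param face_id Identifier for the face; defaults to the file name without
#'   extension (or `"tem"` for literal text input).
#'
#' @return A tibble with columns `face_id`, `point`, `x`, `y`; one row per
#'   landmark, in file order.
#' @seealso [write_tem()], [read_tps()], [validate_landmarks()]
#' @export
#' @examples
#' read_tem("3\n0 0\n1 0\n0 1\n")
read_tem <- function(file, face_id = NULL) {
  lines <- read_input_lines(file)
  if (is.null(face_id)) {
    face_id <- if (attr(lines, "from_file")) {
      sub("\\.[^.]*$", "", basename(file))
    } else "tem"
  }
  parse_tem_lines(as.character(lines), face_id)
}

read_input_lines <- function(file) {
  if (length(file) == 1L && nzchar(file) && !grepl("\n", file)) {
    if (!file.exists(file)) {
      abort(sprintf("file not found: %s", file), class = "facecue_io_error")
    }
    out <- readLines(file, warn = FALSE)
    attr(out, "from_file") <- TRUE
    return(out)
  }
  out <- unlist(strsplit(as.character(file), "\n", fixed = TRUE))
  attr(out, "from_file") <- FALSE
  out
}

parse_tem_lines <- function(lines, face_id) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) {
    abort("empty TEM input", class = "facecue_malformed_error")
  }
  n <- suppressWarnings(as.integer(lines[[1L]]))
  if (is.na(n) || n < 3L) {
    abort("TEM header must be an integer landmark count >= 3",
          class = "facecue_malformed_error")
  }
  coord_lines <- lines[-1L]
  if (length(coord_lines) < n) {
    abort(sprintf(
      "declared %d landmarks but only %d coordinate lines present",
      n, length(coord_lines)
    ), class = "facecue_malformed_error")
  }
  coords <- parse_coord_lines(coord_lines[seq_len(n)])
  tibble::tibble(
    face_id = face_id, point = seq_len(n),
    x = coords[, 1L], y = coords[, 2L]
  )
}

parse_coord_lines <- function(lines) {
  toks <- strsplit(trimws(lines), "[[:space:],]+")
  bad_len <- vapply(toks, length, 1L) < 2L
  if (any(bad_len)) {
    abort(sprintf("coordinate line %d does not hold an x y pair",
                  which(bad_len)[1L]),
          class = "facecue_parse_error")
  }
  xy <- t(vapply(toks, function(t) {
    suppressWarnings(as.numeric(t[1:2]))
  }, numeric(2)))
  if (any(!is.finite(xy))) {
    abort(sprintf("non-numeric coordinate on line %d",
                  which(rowSums(!is.finite(xy)) > 0)[1L]),
          class = "facecue_parse_error")
  }
  xy
}

#' Write a Webmorph TEM landmark file
#'
#' @param landmarks A single-face tidy landmark table (columns `x`, `y`,
#'   optionally `point`) or an n x 2 coordinate matrix, with at least 3
#'   points.
#' @param file Optional path; when `NULL` the TEM text is returned invisibly
#'   as a single string.
#'
#' @return The TEM text, invisibly when written to `file`. Round-tripping
#'   through [read_tem()] preserves the point count exactly and coordinates to
#'   well below 1e-9.
#' @export
write_tem <- function(landmarks, file = NULL) {
  m <- as_landmark_matrix(landmarks)
  if (nrow(m) < 3L) {
    abort("a landmark configuration needs at least 3 points",
          class = "facecue_shape_error")
  }
  if (any(!is.finite(m))) abort("coordinates must be finite")
  txt <- paste0(
    nrow(m), "\n",
    paste(sprintf("%.17g %.17g", m[, 1L], m[, 2L]), collapse = "\n"),
    "\n"
  )
  if (!is.null(file)) {
    writeLines(sub("\n$", "", txt), file)
    return(invisible(txt))
  }
  txt
}

#' Read a TPS landmark file
#'
#' Supports the tpsDig lineage: one or more `LM=n` blocks, each followed by
#' `n` coordinate lines; `ID=` (or `IMAGE=`) keys name the specimen, and other
#' keys (`SCALE=`, comments) are ignored. Several specimens per file are
#' allowed.
#'
#' @inheritParams read_tem
#' @param face_id Optional identifier override; only allowed for single-
#'   specimen files.
#' @return A tibble with columns `face_id`, `point`, `x`, `y`.
#' @export
read_tps <- function(file, face_id = NULL) {
  lines <- trimws(read_input_lines(file))
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (length(starts) == 0L) {
    abort("no LM= record found in TPS input", class = "facecue_malformed_error")
  }
  ends <- c(starts[-1L] - 1L, length(lines))
  specs <- purrr::map2(starts, ends, function(s, e) {
    block <- lines[s:e]
    n <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", block[[1L]],
                                         ignore.case = TRUE)))
    if (is.na(n) || n < 3L) {
      abort("LM= must declare an integer landmark count >= 3",
            class = "facecue_malformed_error")
    }
    body <- block[-1L]
    body <- body[nzchar(body)]
    is_key <- grepl("^[A-Za-z]+\\s*=", body)
    coord_lines <- body[!is_key]
    if (length(coord_lines) < n) {
      abort(sprintf("LM=%d but only %d coordinate lines", n,
                    length(coord_lines)),
            class = "facecue_malformed_error")
    }
    coords <- parse_coord_lines(coord_lines[seq_len(n)])
    keys <- body[is_key]
    id_line <- grep("^(ID|IMAGE)\\s*=", keys, ignore.case = TRUE, value = TRUE)
    id <- if (length(id_line)) {
      sub("^(ID|IMAGE)\\s*=\\s*", "", id_line[[1L]], ignore.case = TRUE)
    } else NA_character_
    list(id = id, coords = coords)
  })
  ids <- purrr::map_chr(specs, "id")
  ids[is.na(ids)] <- paste0("specimen_", which(is.na(ids)))
  if (!is.null(face_id)) {
    if (length(specs) > 1L) {
      abort("`face_id` override only applies to single-specimen TPS files")
    }
    ids <- face_id
  }
  purrr::map2_dfr(specs, ids, function(sp, id) {
    tibble::tibble(face_id = id, point = seq_len(nrow(sp$coords)),
                   x = sp$coords[, 1L], y = sp$coords[, 2L])
  })
}

#' Write a TPS landmark file
#'
#' @param landmarks Tidy landmark table; may contain several faces
#'   (one `LM=` block per `face_id`, in first-appearance order).
#' @param file Optional output path; when `NULL` the text is returned.
#' @return The TPS text, invisibly when written to `file`.
#' @export
write_tps <- function(landmarks, file = NULL) {
  if (is.matrix(landmarks)) {
    landmarks <- array_to_tidy(array(landmarks,
                                     dim = c(nrow(landmarks), 2L, 1L),
                                     dimnames = list(NULL, NULL, "specimen_1")))
  }
  arr <- as_landmark_array(landmarks)
  if (dim(arr)[1L] < 3L) {
    abort("a landmark configuration needs at least 3 points",
          class = "facecue_shape_error")
  }
  blocks <- purrr::map_chr(dimnames(arr)[[3L]], function(id) {
    m <- arr[, , id]
    paste0("LM=", nrow(m), "\n",
           paste(sprintf("%.17g %.17g", m[, 1L], m[, 2L]), collapse = "\n"),
           "\nID=", id, "\n")
  })
  txt <- paste(blocks, collapse = "")
  if (!is.null(file)) {
    writeLines(sub("\n$", "", txt), file)
    return(invisible(txt))
  }
  txt
}

#' Read all landmark files in a directory
#'
#' @param path Directory containing `.tem` and/or `.tps` files.
#' @return A combined tidy landmark tibble, one `face_id` per TEM file (TPS
#'   files may contribute several).
#' @export
read_landmarks <- function(path) {
  files <- list.files(path, pattern = "\\.(tem|tps)$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L) {
    abort(sprintf("no .tem or .tps files under %s", path),
          class = "facecue_io_error")
  }
  purrr::map_dfr(files, function(f) {
    if (grepl("\\.tem$", f, ignore.case = TRUE)) read_tem(f) else read_tps(f)
  })
}

#' Validate landmark files in a directory
#'
#' Attempts to parse every `.tem`/`.tps` file and reports point counts and
#' parse problems per file, without stopping at the first failure.
#'
#' @inheritParams read_landmarks
#' @return A tibble with columns `file`, `format`, `ok`, `n_faces`,
#'   `n_points`, `problem`.
#' @export
validate_landmarks <- function(path) {
  files <- list.files(path, pattern = "\\.(tem|tps)$", ignore.case = TRUE,
                      full.names = TRUE)
  purrr::map_dfr(files, function(f) {
    fmt <- if (grepl("\\.tem$", f, ignore.case = TRUE)) "tem" else "tps"
    res <- tryCatch({
      lm <- if (fmt == "tem") read_tem(f) else read_tps(f)
      tibble::tibble(
        file = basename(f), format = fmt, ok = TRUE,
        n_faces = length(unique(lm$face_id)),
        n_points = nrow(lm) / length(unique(lm$face_id)),
        problem = NA_character_
      )
    }, error = function(e) {
      tibble::tibble(file = basename(f), format = fmt, ok = FALSE,
                     n_faces = 0L, n_points = NA_real_,
                     problem = conditionMessage(e))
    })
    res
  })
}
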