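#' Write a trajectory as multi-frame XYZ
#'
#' Standard XYZ layout per frame: atom-count line, comment line, then one
#' `element x y z` line per atom with 6-decimal positions (A). The comment
#' line carries `key=value` metadata (`time_fs`, `charge`, `seed`, `dt_fs`).
#' Velocities are not part of the XYZ format and are not written.
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj); na <- dim(traj$coords)[2]
  con <- file(path, "w")
  on.exit(close(con))
  meta <- traj$metadata
  for (f in seq_len(nf)) {
    writeLines(as.character(na), con)
    writeLines(sprintf("time_fs=%.6f charge=%s seed=%s dt_fs=%s",
                       traj$times[f],
                       format(meta$total_charge %||% 0),
                       format(meta$seed %||% NA),
                       format(meta$dt_fs %||% NA)), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", traj$elements,
                       traj$coords[f, , 1], traj$coords[f, , 2],
                       traj$coords[f, , 3]), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a multi-frame XYZ trajectory
#'
#' @param path XYZ file written by [write_xyz()] (or any plain XYZ; missing
#'   metadata keys become NA). All frames must share one atom count.
#' @return A `trajectory` (velocities zero: XYZ stores positions only).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  pos <- 1L; frame <- 0L
  coords_list <- list(); times <- numeric(); meta_first <- NULL
  elements <- NULL
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    frame <- frame + 1L
    na <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(na) || na < 1) stop("malformed atom-count line at frame ", frame)
    if (pos + 1 + na > length(lines)) {
      stop("truncated frame ", frame, ": expected ", na, " atom lines")
    }
    comment <- lines[pos + 1]
    block <- lines[(pos + 2):(pos + 1 + na)]
    toks <- strsplit(trimws(block), "[[:space:]]+")
    if (any(lengths(toks) < 4)) stop("malformed coordinate line in frame ", frame)
    el <- purrr::map_chr(toks, 1)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("non-numeric coordinates in frame ", frame)
    if (is.null(elements)) {
      elements <- el
    } else if (length(el) != length(elements)) {
      stop("inconsistent atom count at frame ", frame)
    }
    kv <- .parse_kv(comment)
    times[frame] <- as.numeric(kv[["time_fs"]] %||% (frame - 1))
    if (is.null(meta_first)) meta_first <- kv
    coords_list[[frame]] <- xyz
    pos <- pos + 2L + na
  }
  if (frame == 0) stop("no frames found in ", path)
  na <- length(elements)
  coords <- array(NA_real_, c(frame, na, 3))
  for (f in seq_len(frame)) coords[f, , ] <- coords_list[[f]]
  new_trajectory(
    times, coords, array(0, c(frame, na, 3)), elements,
    metadata = list(
      seed = suppressWarnings(as.integer(meta_first[["seed"]] %||% NA)),
      total_charge = suppressWarnings(as.numeric(meta_first[["charge"]] %||% NA)),
      thermostat = NA,
      dt_fs = suppressWarnings(as.numeric(meta_first[["dt_fs"]] %||%
                                            (if (frame > 1) diff(times[1:2]) else NA)))
    )
  )
}

.parse_kv <- function(line) {
  toks <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  toks <- toks[grepl("=", toks, fixed = TRUE)]
  kv <- strsplit(toks, "=", fixed = TRUE)
  stats::setNames(purrr::map_chr(kv, 2), purrr::map_chr(kv, 1))
}
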