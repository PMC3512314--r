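#' Read a GROMACS-pull-style XVG table
#'
#' Parses the xmgrace text dialect written by MD pull codes: lines starting
#' with `#` are comments (this package stores `# key: value` metadata there),
#' lines starting with `@` are axis/legend directives, and data lines are
#' whitespace-separated numerics with time in the first column.
#'
#' Duplicate time stamps (checkpoint-restart concatenation artifacts) are
#' resolved by keeping the first occurrence, with a warning. Comma decimal
#' separators are rejected rather than guessed: silent locale guessing
#' corrupts data.
#'
#' @param path file to read.
#' @param kind declared content, `"force"` or `"position"` (recorded on the
#'   returned table; the parser itself is kind-agnostic).
#' @return a data.frame (first column `time`), with attributes `metadata`
#'   (named list parsed from `# key: value` lines), `labels` (legend strings
#'   from `@ s<n> legend` lines) and `kind`.
#' @export
read_pull_xvg <- function(path, kind = c("force", "position")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  is_directive <- startsWith(lines, "@")
  is_blank <- !nzchar(trimws(lines))
  data_idx <- which(!is_comment & !is_directive & !is_blank)
  if (length(data_idx) == 0) {
    stop("empty data section in ", path, call. = FALSE)
  }

  meta <- list()
  for (ln in lines[is_comment]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$",
                                ln))[[1]]
    if (length(m) == 3) {
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[m[2]]] <- if (!is.na(num)) num else val
    }
  }
  labels <- character()
  for (ln in lines[is_directive]) {
    m <- regmatches(ln, regexec("^@\\s*s\\d+\\s+legend\\s+\"([^\"]*)\"", ln))[[1]]
    if (length(m) == 2) labels <- c(labels, m[2])
  }

  data_lines <- lines[data_idx]
  has_comma <- grepl(",", data_lines, fixed = TRUE)
  if (any(has_comma)) {
    stop("comma decimal separator (or stray comma) at line ",
         data_idx[which(has_comma)[1]], " of ", path,
         "; this reader only accepts '.' decimals", call. = FALSE)
  }
  parts <- strsplit(trimws(data_lines), "\\s+")
  lens <- lengths(parts)
  ncol_seen <- lens[1]
  if (ncol_seen < 2) {
    stop("data lines need time plus at least one value column (line ",
         data_idx[1], ")", call. = FALSE)
  }
  ragged <- which(lens != ncol_seen)
  if (length(ragged) > 0) {
    stop("ragged row at line ", data_idx[ragged[1]], " of ", path,
         ": expected ", ncol_seen, " columns, found ", lens[ragged[1]],
         call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(parts, use.names = FALSE)))
  if (anyNA(vals)) {
    bad_row <- ceiling(which(is.na(vals))[1] / ncol_seen)
    stop("non-numeric data at line ", data_idx[bad_row], " of ", path,
         call. = FALSE)
  }
  tab <- matrix(vals, ncol = ncol_seen, byrow = TRUE)

  dup <- duplicated(tab[, 1])
  if (any(dup)) {
    warning(sum(dup), " duplicate time stamp(s) in ", path,
            "; keeping first occurrence (restart artifact)", call. = FALSE)
    tab <- tab[!dup, , drop = FALSE]
  }
  df <- as.data.frame(tab)
  names(df) <- c("time", if (length(labels) == ncol(tab) - 1) labels
                 else paste0("V", seq_len(ncol(tab) - 1)))
  attr(df, "metadata") <- meta
  attr(df, "labels") <- labels
  attr(df, "kind") <- kind
  df
}

#' Write a pull trajectory as an XVG file
#'
#' Emits `# key: value` metadata (unit system, protocol constants, replica
#' id), `@` header lines with axis labels and per-series legends, and data
#' rows formatted with 17 significant digits, so a write/read roundtrip
#' reproduces every double exactly. Output is bit-identical for identical
#' input.
#'
#' `kind = "force"` writes time plus the force components; `kind =
#' "position"` writes time, the spring-end components, then the pulled-point
#' components.
#'
#' @param trajectory a [pull_trajectory()].
#' @param path output file.
#' @param kind `"force"` or `"position"`.
#' @return `path`, invisibly.
#' @export
write_pull_xvg <- function(trajectory, path, kind = c("force", "position")) {
  kind <- match.arg(kind)
  stopifnot(inherits(trajectory, "pull_trajectory"))
  dim <- ncol(trajectory$position)
  comp <- if (dim == 3) c("x", "y", "z") else "1"
  unit_labels <- switch(trajectory$units,
    gromacs = c(time = "Time (ps)", force = "Force (kJ/mol/nm)",
                position = "Position (nm)"),
    si = c(time = "Time (s)", force = "Force (N)", position = "Position (m)"),
    c(time = "Time (reduced)", force = "Force (reduced)",
      position = "Position (reduced)")
  )
  if (kind == "force") {
    mat <- cbind(trajectory$time, trajectory$force)
    legends <- paste0("F_", comp)
    yaxis <- unit_labels[["force"]]
    title <- "Pull force"
  } else {
    mat <- cbind(trajectory$time, trajectory$spring_end, trajectory$position)
    legends <- c(paste0("z_spring_", comp), paste0("x_", comp))
    yaxis <- unit_labels[["position"]]
    title <- "Pull position"
  }
  header <- c(
    "# pull trajectory (xvg dialect)",
    sprintf("# units: %s", trajectory$units),
    sprintf("# kind: %s", kind),
    sprintf("# spring_k: %.17g", trajectory$spring_k),
    sprintf("# pull_rate_v: %.17g", trajectory$pull_rate_v),
    sprintf("# temperature_T: %.17g", trajectory$temperature_T),
    sprintf("# replica_id: %d", trajectory$replica_id),
    sprintf("@    title \"%s\"", title),
    sprintf("@    xaxis  label \"%s\"", unit_labels[["time"]]),
    sprintf("@    yaxis  label \"%s\"", yaxis),
    sprintf("@ s%d legend \"%s\"", seq_along(legends) - 1L, legends)
  )
  cols <- lapply(seq_len(ncol(mat)), function(j) sprintf("%.17g", mat[, j]))
  body <- do.call(paste, cols)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con = con, sep = "\n")
  invisible(path)
}

#' Pair force and position tables into a replica set
#'
#' MD pull codes record force and position in separate files; this aligns
#' each force/position pair on their time stamps (within `tolerance`) and
#' assembles [pull_trajectory()] objects from the paired columns and the
#' `# key: value` metadata of the position file.
#'
#' @param force_tables,position_tables equal-length lists of tables from
#'   [read_pull_xvg()]. Position tables must carry spring-end columns
#'   followed by pulled-point columns (as written by [write_pull_xvg()]).
#' @param tolerance maximum |time difference| allowed when pairing rows.
#' @return a [replica_set()].
#' @export
pair_replicas <- function(force_tables, position_tables, tolerance = 1e-6) {
  if (length(force_tables) != length(position_tables)) {
    stop("need equal numbers of force and position tables", call. = FALSE)
  }
  trajs <- vector("list", length(force_tables))
  for (i in seq_along(force_tables)) {
    ft <- force_tables[[i]]
    pt <- position_tables[[i]]
    if (nrow(ft) != nrow(pt)) {
      stop("replica ", i, ": force table has ", nrow(ft),
           " rows but position table has ", nrow(pt), call. = FALSE)
    }
    dt_off <- abs(ft$time - pt$time)
    bad <- which(dt_off > tolerance)
    if (length(bad) > 0) {
      stop(sprintf(paste0("replica %d: time stamps disagree beyond tolerance ",
                          "%g; first offending time %.12g (force) vs %.12g ",
                          "(position)"), i, tolerance,
                   ft$time[bad[1]], pt$time[bad[1]]), call. = FALSE)
    }
    if (max(dt_off) > 0) {
      message(sprintf("replica %d: paired with max time offset %.3g",
                      i, max(dt_off)))
    }
    meta <- attr(pt, "metadata")
    if (is.null(meta)) meta <- list()
    nval <- ncol(pt) - 1L
    if (nval %% 2 != 0) {
      stop("replica ", i, ": position table must hold spring-end columns ",
           "followed by an equal number of pulled-point columns", call. = FALSE)
    }
    dim <- nval %/% 2L
    if (ncol(ft) - 1L != dim) {
      stop("replica ", i, ": force table has ", ncol(ft) - 1L,
           " component(s) but position table implies ", dim, call. = FALSE)
    }
    units <- if (!is.null(meta$units)) meta$units else "reduced"
    trajs[[i]] <- pull_trajectory(
      time = pt$time,
      spring_end = as.matrix(pt[, 1L + seq_len(dim), drop = FALSE]),
      position = as.matrix(pt[, 1L + dim + seq_len(dim), drop = FALSE]),
      force = as.matrix(ft[, -1L, drop = FALSE]),
      spring_k = if (!is.null(meta$spring_k)) meta$spring_k else NA_real_,
      pull_rate_v = if (!is.null(meta$pull_rate_v)) meta$pull_rate_v
                    else NA_real_,
      temperature_T = if (!is.null(meta$temperature_T)) meta$temperature_T
                      else NA_real_,
      units = units,
      replica_id = if (!is.null(meta$replica_id)) meta$replica_id else i
    )
  }
  replica_set(trajs)
}

#' @rdname write_pull_xvg
#' @param set a [replica_set()].
#' @param dir output directory (created if absent); files are named
#'   `pullf_<id>.xvg` and `pullx_<id>.xvg`.
#' @return `write_replica_set()`: the directory, invisibly.
#' @export
write_replica_set <- function(set, dir) {
  stopifnot(inherits(set, "replica_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tr in set$trajectories) {
    write_pull_xvg(tr, file.path(dir, sprintf("pullf_%03d.xvg",
                                              tr$replica_id)), "force")
    write_pull_xvg(tr, file.path(dir, sprintf("pullx_%03d.xvg",
                                              tr$replica_id)), "position")
  }
  invisible(dir)
}

#' @rdname pair_replicas
#' @param dir a directory of `pullf_*.xvg` / `pullx_*.xvg` pairs as written
#'   by [write_replica_set()].
#' @return `read_replica_set()`: a [replica_set()].
#' @export
read_replica_set <- function(dir, tolerance = 1e-6) {
  ff <- sort(list.files(dir, pattern = "^pullf_.*\\.xvg$", full.names = TRUE))
  fx <- sort(list.files(dir, pattern = "^pullx_.*\\.xvg$", full.names = TRUE))
  if (length(ff) == 0) stop("no pullf_*.xvg files in ", dir, call. = FALSE)
  pair_replicas(lapply(ff, read_pull_xvg, kind = "force"),
                lapply(fx, read_pull_xvg, kind = "position"),
                tolerance = tolerance)
}

#' Convert a trajectory between gromacs and SI units
#'
#' @param trajectory a [pull_trajectory()].
#' @param to target unit system.
#' @return the converted trajectory.
#' @export
convert_trajectory <- function(trajectory, to = c("gromacs", "si")) {
  to <- match.arg(to)
  from <- trajectory$units
  if (from == to) return(trajectory)
  tr <- trajectory
  tr$time <- convert_quantity(trajectory$time, "time", from, to)
  tr$spring_end <- convert_quantity(trajectory$spring_end, "length", from, to)
  tr$position <- convert_quantity(trajectory$position, "length", from, to)
  tr$force <- convert_quantity(trajectory$force, "force", from, to)
  # spring_k is energy/length^2: energy factor divided by squared length factor
  f_len <- if (from == "gromacs") .gromacs_to_si[["length"]]
           else 1 / .gromacs_to_si[["length"]]
  f_en <- if (from == "gromacs") .gromacs_to_si[["energy"]]
          else 1 / .gromacs_to_si[["energy"]]
  tr$spring_k <- trajectory$spring_k * f_en / f_len^2
  tr$pull_rate_v <- convert_quantity(trajectory$pull_rate_v, "velocity",
                                     from, to)
  tr$units <- to
  tr
}
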