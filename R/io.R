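# Readers and writers for the motion-capture ecosystem's plain-text formats
# (TRC marker trajectories; MOT/STO time-series tables) and the package's
# JSON model definition.

#' Read a TRC marker trajectory file
#'
#' @param path file path.
#' @return list with `time` (s), `labels`, `coords` (array frames x markers
#'   x 3, metres regardless of the file's unit), `rate` (Hz), `units` ("m").
#' @export
read_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stopf("truncated TRC file (only %d lines): %s",
                               length(lines), path)
  if (!grepl("^PathFileType", lines[1]))
    stopf("malformed TRC header (line 1 must start with PathFileType): %s", path)
  keys <- strsplit(lines[2], "\t")[[1]]
  vals <- strsplit(lines[3], "\t")[[1]]
  hdr <- stats::setNames(as.list(vals), keys)
  need <- c("DataRate", "NumFrames", "NumMarkers", "Units")
  if (!all(need %in% keys))
    stopf("TRC header missing %s", paste(setdiff(need, keys), collapse = ", "))
  rate <- as.numeric(hdr$DataRate)
  n <- as.integer(hdr$NumFrames)
  nm <- as.integer(hdr$NumMarkers)
  unit <- hdr$Units
  scale <- switch(unit, mm = 1e-3, m = 1, cm = 1e-2,
                  stopf("unknown TRC unit '%s'", unit))
  labrow <- strsplit(lines[4], "\t")[[1]]
  labels <- labrow[labrow != ""][-(1:2)]  # Frame#, Time, then markers
  if (length(labels) != nm)
    stopf("TRC label/column mismatch: header says %d markers, found %d",
          nm, length(labels))
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) < n)
    stopf("truncated TRC file: expected %d frames, found %d at line %d",
          n, length(data_lines), 5 + length(data_lines) + 1)
  rows <- lapply(data_lines[seq_len(n)], function(l)
    as.numeric(strsplit(l, "\t")[[1]]))
  ncol_exp <- 2 + 3 * nm
  if (any(vapply(rows, length, 0L) != ncol_exp))
    stopf("TRC data row with wrong column count (expected %d)", ncol_exp)
  tab <- do.call(rbind, rows)
  time <- tab[, 2]
  if (n > 1 && any(diff(time) <= 0)) stopf("non-monotone time in TRC file")
  coords <- array(NA_real_, c(n, nm, 3),
                  dimnames = list(NULL, labels, c("x", "y", "z")))
  for (k in seq_len(nm))
    coords[, k, ] <- tab[, 2 + (3 * (k - 1) + 1):(3 * k)] * scale
  list(time = time, labels = labels, coords = coords, rate = rate,
       units = "m")
}

#' Write a TRC marker trajectory file
#'
#' @param markers list with `time`, `labels`, `coords` (frames x markers x
#'   3, m) as returned by [read_trc()].
#' @param path output path.
#' @param units output unit, `"mm"` (conventional) or `"m"`.
#' @return `path`, invisibly.
#' @export
write_trc <- function(markers, path, units = "mm") {
  scale <- switch(units, mm = 1e3, m = 1, cm = 1e2,
                  stopf("unknown TRC unit '%s'", units))
  n <- length(markers$time)
  nm <- length(markers$labels)
  rate <- if (!is.null(markers$rate)) markers$rate
          else 1 / diff(markers$time[1:2])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines(paste(c("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                     "Units", "OrigDataRate", "OrigDataStartFrame",
                     "OrigNumFrames"), collapse = "\t"), con)
  writeLines(paste(c(rate, rate, n, nm, units, rate, 1, n), collapse = "\t"),
             con)
  writeLines(paste(c("Frame#", "Time",
                     as.vector(rbind(markers$labels, "", ""))),
                   collapse = "\t"), con)
  writeLines(paste(c("", "", paste0(rep(c("X", "Y", "Z"), nm),
                                    rep(seq_len(nm), each = 3))),
                   collapse = "\t"), con)
  for (f in seq_len(n)) {
    row <- c(f, format(markers$time[f], digits = 15))
    for (k in seq_len(nm))
      row <- c(row, format(markers$coords[f, k, ] * scale, digits = 15))
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a MOT/STO time-series file
#'
#' Header key=value lines up to `endheader`, then a tab-separated column
#' table whose first column is time.  Angular columns are converted to
#' radians when the header declares `inDegrees=yes` (columns are treated as
#' angular when their name contains `flexion`, `angle`, or `_rot`).
#'
#' @param path file path.
#' @return data.frame (first column `time`); attribute `"in_degrees"` records
#'   the file flag (values are always returned in radians / SI).
#' @export
read_motsto <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- which(trimws(lines) == "endheader")
  if (!length(end)) stopf("missing endheader in %s", path)
  hdr <- lines[seq_len(end[1] - 1)]
  kv <- list()
  known <- c("version", "nRows", "nColumns", "inDegrees", "name", "DataType")
  for (l in hdr) {
    if (!grepl("=", l, fixed = TRUE)) next
    parts <- strsplit(l, "=", fixed = TRUE)[[1]]
    key <- trimws(parts[1])
    kv[[key]] <- trimws(paste(parts[-1], collapse = "="))
    if (!(key %in% known)) warnf("unknown MOT/STO header key '%s'", key)
  }
  body <- lines[-(seq_len(end[1]))]
  body <- body[nzchar(trimws(body))]
  cols <- strsplit(body[1], "\t")[[1]]
  if (!("time" %in% cols)) stopf("missing time column in %s", path)
  rows <- lapply(body[-1], function(l) as.numeric(strsplit(l, "\t")[[1]]))
  if (any(vapply(rows, length, 0L) != length(cols)))
    stopf("column count mismatch vs header in %s", path)
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- cols
  if (!is.null(kv$nRows) && as.integer(kv$nRows) != nrow(tab))
    stopf("nRows=%s does not match %d data rows in %s", kv$nRows, nrow(tab),
          path)
  if (!is.null(kv$nColumns) && as.integer(kv$nColumns) != ncol(tab))
    stopf("nColumns=%s does not match %d columns in %s", kv$nColumns,
          ncol(tab), path)
  in_deg <- identical(tolower(kv$inDegrees %||% "no"), "yes")
  if (in_deg) {
    ang <- grepl("flexion|angle|_rot", names(tab)) & names(tab) != "time"
    tab[ang] <- tab[ang] * pi / 180
  }
  attr(tab, "in_degrees") <- in_deg
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a MOT/STO time-series file
#'
#' Values are written as stored (SI units, radians); the header declares
#' `inDegrees=no`.
#'
#' @param table data.frame whose first column is `time`.
#' @param path output path.
#' @param name header name field.
#' @return `path`, invisibly.
#' @export
write_motsto <- function(table, path, name = basename(path)) {
  if (names(table)[1] != "time") stopf("first column must be time")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("name=", name), "version=1",
               paste0("nRows=", nrow(table)),
               paste0("nColumns=", ncol(table)),
               "inDegrees=no", "endheader"), con)
  writeLines(paste(names(table), collapse = "\t"), con)
  for (f in seq_len(nrow(table)))
    writeLines(paste(format(as.numeric(table[f, ]), digits = 17),
                     collapse = "\t"), con)
  invisible(path)
}

#' Serialize a model to JSON
#'
#' Versioned schema covering segments, dofs, muscles (with pathways), groups
#' and anthropometry; [read_model_json()] restores it exactly.
#'
#' @param model a [lowerlimb_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    schema = "squatmc-model-1",
    subject_mass = model$subject_mass,
    subject_height = model$subject_height,
    provenance = model$provenance,
    segments = lapply(model$segments, unclass),
    dofs = lapply(model$dofs, unclass),
    muscles = lapply(model$muscles, function(m) {
      m$pathway <- lapply(m$pathway, unclass)
      unclass(m)
    }),
    groups = lapply(model$groups, unclass),
    markers = if (!is.null(model$markers)) as.list(model$markers)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model from JSON
#'
#' @param path a file written by [write_model_json()].
#' @return a [lowerlimb_model()].
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$schema, "squatmc-model-1"))
    stopf("unknown model schema '%s' in %s", obj$schema %||% "<none>", path)
  segs <- lapply(obj$segments, function(s)
    body_segment(s$name, s$mass, unlist(s$com_local), s$inertia_zz, s$length,
                 s$proximal_joint %||% NA_character_,
                 s$distal_joint %||% NA_character_))
  dofs <- lapply(obj$dofs, function(d)
    joint_dof(d$name, d$parent, d$child, d$axis_sign, unlist(d$range),
              unlist(d$location_parent)))
  muscles <- lapply(obj$muscles, function(m)
    mtu(m$name, m$mif, m$tsl, m$pen_opt, m$l_opt,
        lapply(m$pathway, function(p)
          path_point(p$segment, unlist(p$position_local), p$role))))
  groups <- lapply(obj$groups, function(g)
    muscle_group(g$name, unlist(g$members)))
  markers <- if (!is.null(obj$markers))
    data.frame(name = unlist(obj$markers$name),
               segment = unlist(obj$markers$segment),
               x = unlist(obj$markers$x), y = unlist(obj$markers$y),
               stringsAsFactors = FALSE)
  else NULL
  m <- lowerlimb_model(segs, dofs, muscles, groups,
                       subject_mass = obj$subject_mass,
                       subject_height = obj$subject_height,
                       markers = markers,
                       provenance = obj$provenance %||% "baseline")
  m
}

#' Write a simulation result as an STO-style table
#'
#' @param sim a `simulation_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_simulation_sto <- function(sim, path) {
  tab <- data.frame(time = sim$time,
                    kcf_bw = sim$kcf_bw,
                    sim$activations, check.names = FALSE)
  names(tab)[-(1:2)] <- paste0("act_", colnames(sim$activations))
  write_motsto(tab, path, name = "squatmc simulation")
  invisible(path)
}
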