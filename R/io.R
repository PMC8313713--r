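# File-format adapters: GRO and multi-model PDB coordinates (nm internally;
# PDB Angstrom converted on entry), XVG / COLVAR / plain two-column time
# series, and plain-text + JSON round-trips for maps and profiles.

#' Write a snapshot set as GRO files (one per frame)
#'
#' Phosphorus atoms are written with atom name "P" (residue LIP), protein
#' atoms with "CA" (residue PRO). Coordinates are nm, the GRO convention.
#'
#' @param snapshots A `snapshot_set`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_snapshots_gro <- function(snapshots, dir, prefix = "frame") {
  stopifnot(inherits(snapshots, "snapshot_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(snapshots$frames))
  for (f in seq_along(snapshots$frames)) {
    fr <- snapshots$frames[[f]]
    coords <- rbind(fr$upper_P, fr$lower_P, fr$protein_atoms)
    names_at <- c(rep("P", nrow(fr$upper_P) + nrow(fr$lower_P)),
                  rep("CA", nrow(fr$protein_atoms)))
    res <- c(rep("LIP", nrow(fr$upper_P) + nrow(fr$lower_P)),
             rep("PRO", nrow(fr$protein_atoms)))
    n <- nrow(coords)
    lines <- c("synthetic membrane snapshot", sprintf("%d", n),
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       (seq_len(n) - 1L) %% 99999L + 1L, res, names_at,
                       (seq_len(n) - 1L) %% 99999L + 1L,
                       coords[, 1], coords[, 2], coords[, 3]),
               sprintf("%10.5f%10.5f%10.5f",
                       fr$box[1], fr$box[2], fr$box[3]))
    paths[f] <- file.path(dir, sprintf("%s%04d.gro", prefix, f))
    writeLines(lines, paths[f])
  }
  invisible(paths)
}

.parse_gro_frame <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop("truncated GRO file '", path, "': fewer than 3 lines")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("cannot parse atom count at line 2 of '", path, "'")
  if (length(lines) < n + 3L)
    stop("truncated GRO file '", path, "': expected ", n + 3L,
         " lines, found ", length(lines), " (error near line ",
         length(lines), ")")
  at <- lines[3:(n + 2L)]
  name <- trimws(substr(at, 11L, 15L))
  x <- as.numeric(substr(at, 21L, 28L))
  y <- as.numeric(substr(at, 29L, 36L))
  z <- as.numeric(substr(at, 37L, 44L))
  if (any(is.na(x) | is.na(y) | is.na(z))) {
    bad <- which(is.na(x) | is.na(y) | is.na(z))[1] + 2L
    stop("parse error in '", path, "' at line ", bad)
  }
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3L]),
                                              "\\s+")[[1]]))
  if (length(box) < 3L || any(is.na(box[1:3])))
    stop("missing or malformed box line in '", path, "'")
  list(name = name, xyz = cbind(x = x, y = y, z = z), box = box[1:3])
}

# Split one frame's atoms into leaflet phosphorus sets and protein atoms.
# Leaflet assignment: phosphorus z above the frame's mean phosphorus z is
# "upper". The mean midplane sits between the two leaflet clusters even when
# their lipid counts differ (a median would force equal halves).
.frame_from_atoms <- function(name, xyz, box, p_name, protein_names) {
  is_p <- name %in% p_name
  is_prot <- name %in% protein_names
  if (!any(is_p))
    stop("no atoms matched the phosphorus selection '",
         paste(p_name, collapse = ","), "'")
  pz <- xyz[is_p, 3]
  mid <- mean(pz)
  up <- is_p & xyz[, 3] > mid
  lo <- is_p & xyz[, 3] <= mid
  list(upper_P = xyz[up, , drop = FALSE],
       lower_P = xyz[lo, , drop = FALSE],
       protein_atoms = xyz[is_prot, , drop = FALSE],
       box = box)
}

#' Read a snapshot set from GRO files
#'
#' @param paths Character vector of GRO file paths, one frame each.
#' @param p_name Atom name(s) selecting lipid phosphorus (default "P").
#' @param protein_names Atom name(s) selecting protein atoms (default "CA").
#' @return A `snapshot_set`.
#' @export
read_snapshots_gro <- function(paths, p_name = "P", protein_names = "CA") {
  stopifnot(length(paths) >= 1L)
  frames <- lapply(paths, function(p) {
    g <- .parse_gro_frame(p)
    .frame_from_atoms(g$name, g$xyz, g$box, p_name, protein_names)
  })
  structure(list(frames = frames, box = frames[[1]]$box,
                 n_frames = length(frames), spec = NULL),
            class = "snapshot_set")
}

#' Read a snapshot set from a (multi-model) PDB file
#'
#' Coordinates are converted from Angstrom to nm; the box is taken from the
#' CRYST1 record.
#'
#' @param path PDB file path.
#' @param p_name,protein_names Atom-name selections as in
#'   [read_snapshots_gro()].
#' @return A `snapshot_set`.
#' @export
read_snapshots_pdb <- function(path, p_name = "P", protein_names = "CA") {
  cryst <- grep("^CRYST1", readLines(path), value = TRUE)
  if (length(cryst) == 0L)
    stop("missing CRYST1 box in '", path, "'")
  box_a <- suppressWarnings(as.numeric(c(substr(cryst[1], 7, 15),
                                         substr(cryst[1], 16, 24),
                                         substr(cryst[1], 25, 33))))
  if (any(is.na(box_a)))
    stop("missing CRYST1 box in '", path, "'")
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  box <- box_a / 10
  name <- pdb$atom$elety
  nmod <- nrow(pdb$xyz)
  frames <- lapply(seq_len(nmod), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE) / 10
    colnames(xyz) <- c("x", "y", "z")
    .frame_from_atoms(name, xyz, box, p_name, protein_names)
  })
  structure(list(frames = frames, box = box, n_frames = length(frames),
                 spec = NULL),
            class = "snapshot_set")
}

#' Write a snapshot set as a multi-model PDB
#'
#' @param snapshots A `snapshot_set`.
#' @param path Output path. Coordinates written in Angstrom.
#' @return Invisibly, `path`.
#' @export
write_snapshots_pdb <- function(snapshots, path) {
  stopifnot(inherits(snapshots, "snapshot_set"))
  counts <- vapply(snapshots$frames, function(fr)
    nrow(fr$upper_P) + nrow(fr$lower_P) + nrow(fr$protein_atoms), 0L)
  if (length(unique(counts)) != 1L)
    stop("multi-model PDB requires the same atom count in every frame; ",
         "use write_snapshots_gro() for frames with varying lipid counts")
  con <- file(path, "w")
  on.exit(close(con))
  box <- snapshots$box * 10
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     box[1], box[2], box[3], 90, 90, 90), con)
  for (f in seq_along(snapshots$frames)) {
    fr <- snapshots$frames[[f]]
    coords <- rbind(fr$upper_P, fr$lower_P, fr$protein_atoms) * 10
    names_at <- c(rep("P", nrow(fr$upper_P) + nrow(fr$lower_P)),
                  rep("CA", nrow(fr$protein_atoms)))
    res <- c(rep("LIP", nrow(fr$upper_P) + nrow(fr$lower_P)),
             rep("PRO", nrow(fr$protein_atoms)))
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      (seq_len(nrow(coords)) - 1L) %% 99999L + 1L, names_at, res,
      (seq_len(nrow(coords)) - 1L) %% 9999L + 1L,
      coords[, 1], coords[, 2], coords[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a reaction-coordinate time series
#'
#' Supports plain two-column text, XVG (lines starting with `@` or `#`
#' skipped) and COLVAR files (a `#! FIELDS time ...` header names the
#' columns).
#'
#' @param path File path.
#' @param dialect `"auto"`, `"plain"`, `"xvg"` or `"colvar"`.
#' @param column Value column: index (default 2) or, for COLVAR, a field
#'   name.
#' @return A list with `time`, `value` and `fields`.
#' @export
read_timeseries <- function(path, dialect = c("auto", "plain", "xvg", "colvar"),
                            column = 2L) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  fields <- NULL
  if (dialect == "auto") {
    dialect <- if (any(startsWith(lines, "#! FIELDS"))) "colvar"
    else if (any(startsWith(lines, "@"))) "xvg"
    else "plain"
  }
  if (dialect == "colvar") {
    hdr <- lines[startsWith(lines, "#! FIELDS")][1]
    if (!is.na(hdr))
      fields <- strsplit(trimws(sub("^#! FIELDS", "", hdr)), "\\s+")[[1]]
  }
  data_lines <- lines[!startsWith(lines, "@") & !startsWith(lines, "#") &
                        nzchar(trimws(lines))]
  if (length(data_lines) < 2L)
    stop("need at least 2 numeric rows in '", path, "'")
  mat <- do.call(rbind, lapply(data_lines, function(l)
    suppressWarnings(as.numeric(strsplit(trimws(l), "[[:space:],]+")[[1]]))))
  if (any(is.na(mat)))
    stop("non-numeric data in '", path, "'")
  if (is.character(column)) {
    if (is.null(fields) || !(column %in% fields))
      stop("column '", column, "' not found in COLVAR FIELDS header")
    column <- match(column, fields)
  }
  tm <- mat[, 1]
  if (any(diff(tm) <= 0))
    stop("non-monotonic time column in '", path, "'")
  dt <- diff(tm)
  if (max(dt) > 1.5 * stats::median(dt))
    warning("non-uniform time spacing in '", path, "' (possible gaps)")
  list(time = tm, value = mat[, column], fields = fields)
}

#' Write umbrella-window series as COLVAR-style text files
#'
#' @param dataset An `umbrella_dataset`.
#' @param dir Output directory.
#' @param dt Time spacing written in the first column.
#' @return Invisibly, a data frame manifest (file, center, k) also written
#'   as `windows.csv` in `dir`.
#' @export
write_umbrella_series <- function(dataset, dir, dt = 1) {
  stopifnot(inherits(dataset, "umbrella_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- data.frame(file = character(0), center = numeric(0), k = numeric(0))
  for (i in seq_along(dataset$windows)) {
    w <- dataset$windows[[i]]
    fn <- sprintf("window%02d.colvar", i)
    con <- file(file.path(dir, fn), "w")
    writeLines("#! FIELDS time d1", con)
    writeLines(sprintf("%.6g %.10g", seq_along(w$series) * dt, w$series), con)
    close(con)
    man <- rbind(man, data.frame(file = fn, center = w$center, k = w$k))
  }
  utils::write.csv(man, file.path(dir, "windows.csv"), row.names = FALSE)
  invisible(man)
}

#' Read an umbrella dataset from a window manifest
#'
#' The manifest is a CSV with columns `file`, `center` (nm) and `k`
#' (kJ mol^-1 nm^-2); series files are resolved relative to the manifest.
#'
#' @param manifest Path to the manifest CSV.
#' @param temperature Kelvin.
#' @param column Value column passed to [read_timeseries()].
#' @return An `umbrella_dataset`.
#' @export
read_umbrella_dataset <- function(manifest, temperature = 320, column = 2L) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  req <- c("file", "center", "k")
  if (!all(req %in% names(man)))
    stop("manifest must have columns: ", paste(req, collapse = ", "))
  base <- dirname(manifest)
  series <- lapply(man$file, function(f)
    read_timeseries(file.path(base, f), column = column)$value)
  umbrella_dataset(series, man$center, man$k, temperature = temperature)
}

#' Write a thickness map as plain-text matrix plus JSON metadata
#'
#' @param tmap A `thickness_map`.
#' @param prefix Output path prefix; writes `<prefix>.tsv` (full-precision
#'   matrix), `<prefix>_nobs.tsv`, and `<prefix>.json` metadata.
#' @return Invisibly, the metadata list.
#' @export
write_thickness_map <- function(tmap, prefix) {
  stopifnot(inherits(tmap, "thickness_map"))
  utils::write.table(format(tmap$mean_thickness, digits = 17L),
                     paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(tmap$n_obs, paste0(prefix, "_nobs.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  meta <- list(nx = tmap$grid$nx, ny = tmap$grid$ny,
               box_x = tmap$grid$box_x, box_y = tmap$grid$box_y,
               h_bulk = tmap$h_bulk,
               interpolated = which(as.vector(tmap$interpolated)))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(meta)
}

#' Read a thickness map written by [write_thickness_map()]
#' @param prefix Path prefix used when writing.
#' @return A `thickness_map`.
#' @export
read_thickness_map <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  g <- grid_spec(meta$nx, meta$ny, meta$box_x, meta$box_y)
  m <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t"))
  dimnames(m) <- NULL
  n <- as.matrix(utils::read.table(paste0(prefix, "_nobs.tsv"), sep = "\t"))
  dimnames(n) <- NULL
  interp <- matrix(FALSE, meta$nx, meta$ny)
  interp[unlist(meta$interpolated)] <- TRUE
  structure(list(grid = g, mean_thickness = m, n_obs = n,
                 interpolated = interp, h_bulk = meta$h_bulk),
            class = "thickness_map")
}

#' Write a free-energy profile as CSV
#' @param profile A `free_energy_profile`.
#' @param path Output CSV path (columns x, F, sigma_F).
#' @return Invisibly, `path`.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "free_energy_profile"))
  df <- data.frame(x = profile$x, F = profile$F,
                   sigma_F = if (is.null(profile$sigma_F)) NA_real_
                   else profile$sigma_F)
  utils::write.csv(format(df, digits = 17L), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
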