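# File formats: PDB (topology + multi-model coordinates), CHARMM/NAMD DCD
# (single precision, Fortran record markers), OpenDX scalar grids, flat
# key:value config files, and CSV artifacts with a metadata header line.

#' Write a topology (with reference or trajectory coordinates) as PDB
#'
#' Multi-frame input produces a multi-model PDB (MODEL/ENDMDL records).
#' A CRYST1 record is emitted when the topology carries a box.
#'
#' @param x an [lp_trajectory()] or an [lp_topology()] with x/y/z columns
#' @param path output file
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "lp_topology")) {
    if (!all(c("x", "y", "z") %in% names(x$atoms)))
      stop("topology has no reference coordinates; pass a trajectory")
    coords <- array(as.matrix(x$atoms[, c("x", "y", "z")]),
                    dim = c(1L, nrow(x$atoms), 3L))
    top <- x
  } else {
    stopifnot(inherits(x, "lp_trajectory"))
    coords <- x$coords
    top <- x$top
  }
  at <- top$atoms
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(top$box))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       top$box[1], top$box[2], top$box[3], 90, 90, 90), con)
  nf <- dim(coords)[1]
  lig_ids <- .ligand_atom_ids(top)
  rec <- ifelse(at$atom_id %in% lig_ids, "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(at$name) < 4, sprintf(" %-3s", at$name), sprintf("%-4s", at$name))
  for (f in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL     %4d", f), con)
    lines <- sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rec, (at$atom_id %% 99999L) + 1L, name4,
                     substr(at$residue_name, 1, 3), substr(at$chain_id, 1, 1),
                     at$residue_id %% 10000L,
                     coords[f, , 1], coords[f, , 2], coords[f, , 3],
                     1, 0, at$element)
    writeLines(lines, con)
    if (nf > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a PDB file into an atom table and coordinates
#'
#' @param path PDB file
#' @return list with `atoms` (data.frame ready for [lp_topology()]),
#'   `coords` (frames x atoms x 3 array) and `box` (numeric(3) or NULL)
#' @export
read_pdb <- function(path) {
  ln <- readLines(path)
  box <- NULL
  cr <- ln[startsWith(ln, "CRYST1")]
  if (length(cr) > 0)
    box <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24), substr(cr[1], 25, 33)))
  is_atom <- startsWith(ln, "ATOM") | startsWith(ln, "HETATM")
  model_breaks <- cumsum(startsWith(ln, "MODEL"))
  if (max(model_breaks) == 0) model_breaks <- rep(1L, length(ln))
  al <- ln[is_atom]
  mb <- model_breaks[is_atom]
  first <- al[mb == mb[1]]
  atoms <- data.frame(
    atom_id = seq_along(first) - 1L,
    name = trimws(substr(first, 13, 16)),
    element = trimws(substr(first, 77, 78)),
    residue_id = as.integer(substr(first, 23, 26)),
    residue_name = trimws(substr(first, 18, 21)),
    chain_id = trimws(substr(first, 22, 22)),
    stringsAsFactors = FALSE
  )
  blank <- atoms$element == ""
  atoms$element[blank] <- substr(atoms$name[blank], 1, 1)
  nf <- length(unique(mb))
  na <- nrow(atoms)
  if (length(al) != nf * na) stop("inconsistent atom count across PDB models")
  xyz <- cbind(as.numeric(substr(al, 31, 38)),
               as.numeric(substr(al, 39, 46)),
               as.numeric(substr(al, 47, 54)))
  coords <- array(NA_real_, dim = c(nf, na, 3))
  for (f in seq_len(nf)) coords[f, , ] <- xyz[((f - 1) * na + 1):(f * na), ]
  list(atoms = atoms, coords = coords, box = box)
}

#' Write coordinates as a CHARMM/NAMD-style DCD trajectory
#'
#' Single-precision, little-endian on this platform, with a unit-cell record
#' per frame when the topology has a box.
#'
#' @param traj an [lp_trajectory()]
#' @param path output file
#' @param dt frame spacing written into the header (AKMA-agnostic; stored
#'   verbatim and returned by [read_dcd()])
#' @export
write_dcd <- function(traj, path, dt = 1) {
  coords <- traj$coords
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  has_cell <- !is.null(traj$top$box)
  con <- file(path, "wb")
  on.exit(close(con))
  wrec <- function(writer) {
    # write payload to raw first so the Fortran record length is exact
    rc <- rawConnection(raw(0), "wb")
    writer(rc)
    payload <- rawConnectionValue(rc)
    close(rc)
    writeBin(length(payload), con, size = 4L)
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4L)
  }
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[11] <- as.integer(has_cell)
  icntrl[20] <- 24L
  wrec(function(c2) {
    writeBin(charToRaw("CORD"), c2)
    writeBin(icntrl[1:9], c2, size = 4L)
    writeBin(as.numeric(dt), c2, size = 4L)  # DELTA as float
    writeBin(icntrl[11:20], c2, size = 4L)
  })
  title <- sprintf("%-80s", "ligpath trajectory")
  wrec(function(c2) { writeBin(1L, c2, size = 4L); writeBin(charToRaw(title), c2) })
  wrec(function(c2) writeBin(as.integer(na), c2, size = 4L))
  box <- traj$top$box
  for (f in seq_len(nf)) {
    if (has_cell)
      wrec(function(c2) writeBin(as.numeric(c(box[1], 90, box[2], 90, 90, box[3])),
                                 c2, size = 8L))
    for (k in 1:3) {
      xk <- as.numeric(coords[f, , k])
      wrec(function(c2) writeBin(xk, c2, size = 4L))
    }
  }
  invisible(path)
}

#' Read a DCD trajectory
#'
#' @param path DCD file
#' @return list with `coords` (frames x atoms x 3, single precision),
#'   `box` (numeric(3) or NULL, from the first frame's cell record) and
#'   `dt` (header DELTA)
#' @export
read_dcd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rrec <- function() {
    n <- readBin(con, "integer", 1, size = 4L)
    if (length(n) == 0) return(NULL)
    payload <- readBin(con, "raw", n)
    n2 <- readBin(con, "integer", 1, size = 4L)
    if (!identical(n, n2)) stop("corrupt DCD record (marker mismatch)")
    payload
  }
  hdr <- rrec()
  if (rawToChar(hdr[1:4]) != "CORD") stop("not a DCD file")
  ints <- readBin(hdr[5:84], "integer", 20, size = 4L)
  nf <- ints[1]
  dt <- readBin(hdr[(4 + 9 * 4 + 1):(4 + 10 * 4)], "numeric", 1, size = 4L)
  has_cell <- ints[11] == 1L
  rrec()  # titles
  na <- readBin(rrec(), "integer", 1, size = 4L)
  coords <- array(NA_real_, dim = c(nf, na, 3))
  box <- NULL
  for (f in seq_len(nf)) {
    if (has_cell) {
      cell <- readBin(rrec(), "numeric", 6, size = 8L)
      if (f == 1) box <- cell[c(1, 3, 6)]
    }
    for (k in 1:3)
      coords[f, , k] <- readBin(rrec(), "numeric", na, size = 4L)
  }
  list(coords = coords, box = box, dt = dt)
}

#' Write a 3D scalar grid in OpenDX format
#'
#' @param grid an `lp_grid` as produced by [occupancy_density()], or any list
#'   with `origin` (numeric 3), `spacing` (numeric 1 or 3) and `counts`
#'   (3D array)
#' @param path output file
#' @export
write_dx <- function(grid, path) {
  a <- grid$counts
  stopifnot(length(dim(a)) == 3)
  sp <- rep(grid$spacing, length.out = 3)
  n <- dim(a)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.6f %.6f %.6f", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0 0", sp[1]),
    sprintf("delta 0 %.6f 0", sp[2]),
    sprintf("delta 0 0 %.6f", sp[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", prod(n))
  ), con)
  # DX fastest-varying index is z
  v <- as.numeric(aperm(a, c(3, 2, 1)))
  pad <- (-length(v)) %% 3
  vv <- c(v, rep(NA_real_, pad))
  m <- matrix(vv, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r) paste(formatC(r[!is.na(r)], format = "g", digits = 7),
                                         collapse = " "))
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Parse a flat key: value configuration file
#'
#' Supports one `key: value` pair per line, `#` comments, numeric and
#' logical coercion, and comma-separated lists. This is a deliberate flat
#' subset of YAML sufficient for run configuration; nested structures are
#' not supported.
#'
#' @param path config file
#' @return named list
#' @export
read_config <- function(path) {
  ln <- readLines(path)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  out <- list()
  for (l in ln) {
    if (!grepl(":", l, fixed = TRUE)) stop("config line without ':': ", l)
    key <- trimws(sub(":.*$", "", l))
    val <- trimws(sub("^[^:]*:", "", l))
    parts <- trimws(strsplit(val, ",")[[1]])
    coerce <- function(s) {
      if (tolower(s) %in% c("true", "yes")) return(TRUE)
      if (tolower(s) %in% c("false", "no")) return(FALSE)
      n <- suppressWarnings(as.numeric(s))
      if (!is.na(n)) n else s
    }
    v <- lapply(parts, coerce)
    if (length(v) == 1) v <- v[[1]] else {
      if (all(vapply(v, is.numeric, logical(1)))) v <- unlist(v) else v <- unlist(lapply(v, as.character))
    }
    out[[key]] <- v
  }
  out
}

#' Write a flat key: value configuration file
#' @param config named list of scalars or atomic vectors
#' @param path output file
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s: %s", k, paste(format(v, scientific = FALSE, trim = TRUE), collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# short md5-based fingerprint of a config list (drives output provenance)
.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  if (length(config) > 0) config <- config[order(names(config))]
  write_config(config, tmp)
  substr(unname(tools::md5sum(tmp)), 1, 12)
}

#' Write a data.frame as CSV with a provenance header line
#'
#' First line is `# ligpath <version> config=<hash>`; readers obtained with
#' [read_ligpath_csv()] skip it.
#' @param df data.frame
#' @param path output file
#' @param config optional config list hashed into the header
#' @export
write_ligpath_csv <- function(df, path, config = list()) {
  ver <- as.character(utils::packageVersion("ligpath"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ligpath %s config=%s", ver, .config_hash(config)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_ligpath_csv()]
#' @param path CSV file
#' @export
read_ligpath_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read umbrella-window samples from CSV
#'
#' Expected columns: `window_id, center1, center2, k, temperature, xi1, xi2`
#' (one row per frame).
#' @param path CSV file
#' @return list of umbrella windows as consumed by [wham2d()]
#' @export
read_umbrella_csv <- function(path) {
  df <- read_ligpath_csv(path)
  req <- c("window_id", "center1", "center2", "k", "temperature", "xi1", "xi2")
  if (!all(req %in% names(df))) stop("umbrella CSV needs columns: ",
                                     paste(req, collapse = ", "))
  lapply(split(df, df$window_id), function(w) {
    umbrella_window(center = c(w$center1[1], w$center2[1]), k = w$k[1],
                    samples = cbind(w$xi1, w$xi2), temperature = w$temperature[1])
  })
}

#' Write umbrella windows to CSV
#' @param windows list of [umbrella_window()] objects
#' @param path output file
#' @param config optional config for the provenance header
#' @export
write_umbrella_csv <- function(windows, path, config = list()) {
  dfs <- lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    data.frame(window_id = i - 1L, center1 = w$center[1], center2 = w$center[2],
               k = w$k, temperature = w$temperature,
               xi1 = w$samples[, 1], xi2 = w$samples[, 2])
  })
  write_ligpath_csv(do.call(rbind, dfs), path, config)
}
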