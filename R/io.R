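#' Trajectory readers and writers
#'
#' Three plain-text dialects are supported. Extended XYZ: per frame a count
#' line, a comment line `box=<L> time=<t>`, then `species x y z q` rows.
#' LAMMPS dump: the usual `ITEM: TIMESTEP / NUMBER OF ATOMS / BOX BOUNDS /
#' ATOMS id type q x y z` blocks with type codes 1 = monomer, 2 = ion_mono,
#' 3 = ion_tri (coordinates wrapped into the box on export). Native: a
#' self-describing container that stores the topology, species, charges,
#' and *unwrapped* full-precision coordinates, so that write-then-read is
#' bit-identical.
#'
#' @param traj a `ringstack_trajectory` (writers) / file path (readers).
#' @param path file path.
#' @param topology a [ring_topology()] to attach when the format does not
#'   carry one (XYZ, dump).
#' @return readers return a `ringstack_trajectory`.
#' @name trajectory_io
NULL

species_type <- c(monomer = 1L, ion_mono = 2L, ion_tri = 3L)

#' @rdname trajectory_io
#' @export
write_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in traj$frames) {
    writeLines(as.character(nrow(fr$positions)), con)
    writeLines(sprintf("box=%.17g time=%.17g", fr$box_length, fr$time), con)
    writeLines(sprintf("%s %.17g %.17g %.17g %.17g", fr$species,
                       fr$positions[, 1], fr$positions[, 2],
                       fr$positions[, 3], fr$charges), con)
  }
  invisible(path)
}

#' @rdname trajectory_io
#' @export
read_xyz <- function(path, topology = NULL) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  fidx <- 0
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    fidx <- fidx + 1
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) stop(sprintf("malformed frame %d: bad count line", fidx))
    hdr <- lines[i + 1]
    box <- as.numeric(sub(".*box=([0-9eE.+-]+).*", "\\1", hdr))
    tm <- as.numeric(sub(".*time=([0-9eE.+-]+).*", "\\1", hdr))
    if (i + 1 + n > length(lines))
      stop(sprintf("malformed frame %d: truncated", fidx))
    rows <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "\\s+")
    if (any(lengths(rows) < 4))
      stop(sprintf("malformed frame %d: bad atom line", fidx))
    sp <- vapply(rows, `[`, "", 1)
    num <- t(vapply(rows, function(r) as.numeric(r[2:min(5, length(r))]),
                    numeric(min(5, length(rows[[1]])) - 1)))
    q <- if (ncol(num) >= 4) num[, 4] else rep(0, n)
    frames[[fidx]] <- configuration(num[, 1:3], sp, q, box, tm)
    i <- i + 2 + n
  }
  if (length(frames) == 0) stop("no frames in file")
  make_read_trajectory(frames, topology)
}

#' @rdname trajectory_io
#' @export
write_lammps_dump <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in traj$frames) {
    n <- nrow(fr$positions)
    wrapped <- fr$positions %% fr$box_length
    writeLines(c("ITEM: TIMESTEP", sprintf("%d", round(fr$time / 0.005)),
                 "ITEM: NUMBER OF ATOMS", sprintf("%d", n),
                 "ITEM: BOX BOUNDS pp pp pp",
                 rep(sprintf("0 %.17g", fr$box_length), 3),
                 "ITEM: ATOMS id type q x y z"), con)
    writeLines(sprintf("%d %d %.17g %.17g %.17g %.17g", seq_len(n),
                       species_type[fr$species], fr$charges, wrapped[, 1],
                       wrapped[, 2], wrapped[, 3]), con)
  }
  invisible(path)
}

#' @rdname trajectory_io
#' @export
read_lammps_dump <- function(path, topology = NULL) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  fidx <- 0
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "ITEM: TIMESTEP")) { i <- i + 1; next }
    fidx <- fidx + 1
    step <- as.numeric(lines[i + 1])
    if (!startsWith(lines[i + 2], "ITEM: NUMBER OF ATOMS"))
      stop(sprintf("malformed frame %d", fidx))
    n <- as.integer(lines[i + 3])
    lo_hi <- strsplit(trimws(lines[i + 5]), "\\s+")[[1]]
    box <- as.numeric(lo_hi[2]) - as.numeric(lo_hi[1])
    cols <- strsplit(sub("ITEM: ATOMS ", "", lines[i + 8]), "\\s+")[[1]]
    if (i + 8 + n > length(lines))
      stop(sprintf("malformed frame %d: truncated", fidx))
    dat <- do.call(rbind,
                   lapply(strsplit(trimws(lines[(i + 9):(i + 8 + n)]),
                                   "\\s+"), as.numeric))
    colnames(dat) <- cols
    dat <- dat[order(dat[, "id"]), , drop = FALSE]
    sp <- names(species_type)[dat[, "type"]]
    q <- if ("q" %in% cols) unname(dat[, "q"]) else rep(0, n)
    pos <- dat[, c("x", "y", "z")]
    dimnames(pos) <- NULL
    frames[[fidx]] <- configuration(pos, sp, q, box, time = step * 0.005)
    i <- i + 9 + n
  }
  if (length(frames) == 0) stop("no frames in file")
  make_read_trajectory(frames, topology)
}

#' @rdname trajectory_io
#' @export
write_native <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  topo <- traj$topology
  writeLines("ringstack-trajectory 1", con)
  writeLines(sprintf("rings %d", topo$M), con)
  for (m in seq_len(topo$M))
    writeLines(sprintf("ring %s %s",
                       if (topo$closed[m]) "closed" else "open",
                       paste(topo$rings[[m]], collapse = " ")), con)
  fr1 <- traj$frames[[1]]
  writeLines(sprintf("species %s", paste(fr1$species, collapse = " ")), con)
  writeLines(sprintf("charges %s",
                     paste(sprintf("%.17g", fr1$charges), collapse = " ")),
             con)
  for (fr in traj$frames) {
    writeLines(sprintf("frame %.17g %.17g %d", fr$time, fr$box_length,
                       nrow(fr$positions)), con)
    writeLines(sprintf("%.17g %.17g %.17g", fr$positions[, 1],
                       fr$positions[, 2], fr$positions[, 3]), con)
  }
  invisible(path)
}

#' @rdname trajectory_io
#' @export
read_native <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "ringstack-trajectory 1"))
    stop("not a ringstack native trajectory")
  M <- as.integer(sub("rings ", "", lines[2]))
  rings <- list()
  closed <- logical(M)
  i <- 3
  for (m in seq_len(M)) {
    parts <- strsplit(lines[i], " ")[[1]]
    closed[m] <- parts[2] == "closed"
    rings[[m]] <- as.integer(parts[-(1:2)])
    i <- i + 1
  }
  topo <- ring_topology(rings, closed)
  species <- strsplit(sub("species ", "", lines[i]), " ")[[1]]
  charges <- as.numeric(strsplit(sub("charges ", "", lines[i + 1]), " ")[[1]])
  i <- i + 2
  frames <- list()
  fidx <- 0
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "frame")) { i <- i + 1; next }
    fidx <- fidx + 1
    hdr <- as.numeric(strsplit(lines[i], " ")[[1]][-1])
    n <- as.integer(hdr[3])
    if (i + n > length(lines))
      stop(sprintf("malformed frame %d: truncated", fidx))
    pos <- do.call(rbind, lapply(strsplit(lines[(i + 1):(i + n)], " "),
                                 as.numeric))
    frames[[fidx]] <- configuration(pos, species, charges, hdr[2], hdr[1])
    i <- i + n + 1
  }
  if (fidx == 0) stop("no frames in file")
  make_read_trajectory(frames, topo)
}

make_read_trajectory <- function(frames, topology) {
  structure(list(frames = frames, topology = topology,
                 final_velocities = NULL, kinetic_per_dof = NULL,
                 protocol = NULL),
            class = "ringstack_trajectory")
}

#' @rdname trajectory_io
#' @param format one of `"native"`, `"xyz"`, `"lammps_dump"`.
#' @export
read_trajectory <- function(path, format = c("native", "xyz", "lammps_dump"),
                            topology = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  switch(format,
         native = read_native(path),
         xyz = read_xyz(path, topology),
         lammps_dump = read_lammps_dump(path, topology))
}
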