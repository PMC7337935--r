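# Readers/writers for the oxDNA plain-text dialects and viewer overlay JSON.
#
# All readers accept both Unix and Windows newlines; all writers emit Unix
# newlines. Round trips are value-identical at the emitter's precision.

.read_lines <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  readLines(path, warn = FALSE)
}

#' Read an oxDNA topology file
#'
#' The classic dialect: a header line `N n_strands` followed by one line per
#' nucleotide with columns `strand base neighbor_3 neighbor_5`, where -1
#' encodes a missing neighbour. Connectivity is validated (mutual links,
#' single path or cycle per strand); circular strands are detected from the
#' links.
#'
#' @param path Path to the topology file.
#' @return An `oxdna_topology`.
#' @export
read_topology <- function(path) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) .stopf("topology %s: empty file", path)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) < 2L || anyNA(hdr[1:2]))
    .stopf("topology %s: malformed header '%s'", path, lines[1])
  n <- hdr[1]
  if (length(lines) - 1L != n)
    .stopf("topology %s: header declares %d nucleotides but body has %d lines (line %d)",
           path, n, length(lines) - 1L, length(lines))
  fields <- strsplit(trimws(lines[-1]), "\\s+")
  bad <- which(lengths(fields) < 4L)
  if (length(bad))
    .stopf("topology %s: malformed body at line %d", path, bad[1] + 1L)
  m <- do.call(rbind, fields)
  nb3 <- as.integer(m[, 3]); nb5 <- as.integer(m[, 4])
  nb3[nb3 == -1L] <- NA_integer_
  nb5[nb5 == -1L] <- NA_integer_
  topo <- topology(strand_id = as.integer(m[, 1]), base = m[, 2],
                   neighbor3 = nb3, neighbor5 = nb5)
  if (topo$n_strands != hdr[2])
    warning(sprintf("topology %s: header declares %d strands, found %d",
                    path, hdr[2], topo$n_strands))
  topo
}

#' Write an oxDNA topology file
#'
#' @param topo An `oxdna_topology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topo, path) {
  nb3 <- ifelse(is.na(topo$neighbor3), -1L, topo$neighbor3)
  nb5 <- ifelse(is.na(topo$neighbor5), -1L, topo$neighbor5)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(sprintf("%d %d", topo$n, topo$n_strands),
               sprintf("%d %s %d %d", topo$strand_id, topo$base, nb3, nb5)),
             con, sep = "\n")
  invisible(path)
}

# Parse one frame block (3 header lines + N particle lines).
.parse_frame <- function(lines, n, frame_idx) {
  if (length(lines) < 3L + n)
    .stopf("frame %d: expected %d particle lines, found %d",
           frame_idx, n, max(0L, length(lines) - 3L))
  t_val <- as.numeric(sub("^t\\s*=\\s*", "", lines[1]))
  box <- as.numeric(strsplit(trimws(sub("^b\\s*=\\s*", "", lines[2])),
                             "\\s+")[[1]])
  en <- as.numeric(strsplit(trimws(sub("^E\\s*=\\s*", "", lines[3])),
                            "\\s+")[[1]])
  body <- lines[3L + seq_len(n)]
  vals <- suppressWarnings(
    scan(text = body, what = numeric(), quiet = TRUE, multi.line = FALSE))
  ncol_line <- length(vals) / n
  if (ncol_line != floor(ncol_line) || ncol_line < 9)
    .stopf("frame %d: particle lines must have >= 9 numeric columns",
           frame_idx)
  m <- matrix(vals, nrow = n, byrow = TRUE)
  a1 <- m[, 4:6, drop = FALSE]
  a3 <- m[, 7:9, drop = FALSE]
  for (nm in c("a1", "a3")) {
    v <- get(nm)
    norms <- sqrt(rowSums(v^2))
    if (any(abs(norms - 1) > 1e-3))
      .stopf("frame %d: non-unit %s versor (deviation %.2e beyond 1e-3)",
             frame_idx, nm, max(abs(norms - 1)))
    assign(nm, v / norms)
  }
  # restore orthogonality lost to limited printing precision
  dots <- rowSums(a1 * a3)
  if (any(abs(dots) > 1e-10)) {
    a1 <- a1 - dots * a3
    a1 <- a1 / sqrt(rowSums(a1^2))
  }
  configuration(positions = m[, 1:3, drop = FALSE], a1 = a1, a3 = a3,
                time = t_val, box = box, energies = en)
}

#' Read an oxDNA configuration/trajectory file
#'
#' Each frame is a block of `t = ...`, `b = ...`, `E = ...` header lines
#' followed by one line per particle with at least 9 columns (position, a1,
#' a3; velocities, if present, are parsed but ignored by every analysis).
#' A single indexing pass records the byte offset of each `t =` line; frames
#' are parsed lazily on access, so large files cost only one scan up front.
#' Versors off unit length by at most 1e-3 are re-normalised; worse ones are
#' rejected.
#'
#' @param path Path to the file.
#' @param topo The shared `oxdna_topology`.
#' @return A file-backed `oxdna_traj`.
#' @export
read_trajectory <- function(path, topo) {
  lines <- .read_lines(path)
  nbytes <- nchar(lines, type = "bytes") + 1L  # + newline
  offsets_all <- c(0, cumsum(as.numeric(nbytes)))
  starts <- grep("^t\\s*=", lines)
  if (length(starts) == 0L) .stopf("%s: no frame headers found", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  for (k in seq_along(starts)) {
    body <- sum(nzchar(trimws(lines[(starts[k] + 3L):ends[k]])))
    if (starts[k] + 2L > ends[k] || body != topo$n)
      .stopf("frame %d: expected %d particle lines, found %d", k, topo$n,
             max(0L, body))
  }
  traj <- structure(
    list(topology = topo, frames = NULL, n_frames = length(starts),
         path = normalizePath(path), offsets = offsets_all[starts],
         block_lines = ends - starts + 1L),
    class = "oxdna_traj"
  )
  # validate eagerly so malformed versors fail at read time, not first use
  for (k in seq_len(traj$n_frames)) get_frame(traj, k)
  traj
}

# O(1) seek + parse of frame k in a file-backed trajectory.
.read_frame_at <- function(traj, k) {
  con <- file(traj$path, "rb")
  on.exit(close(con))
  seek(con, where = traj$offsets[k], origin = "start")
  lines <- readLines(con, n = traj$block_lines[k], warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  .parse_frame(lines, traj$topology$n, k)
}

.fmt_conf <- function(conf, precision) {
  n <- nrow(conf$positions)
  fmt <- sprintf("%%.%df", precision)
  num <- cbind(conf$positions, conf$a1, conf$a3,
               matrix(0, n, 6))  # velocities/angular velocities: zeros
  body <- apply(num, 1L, function(r) paste(sprintf(fmt, r), collapse = " "))
  c(sprintf("t = %s", format(conf$time, scientific = FALSE)),
    sprintf("b = %s", paste(sprintf(fmt, conf$box), collapse = " ")),
    sprintf("E = %s", paste(sprintf(fmt, conf$energies), collapse = " ")),
    body)
}

#' Write an oxDNA trajectory (or single configuration) file
#'
#' Frames are emitted in order, each as the standard three header lines plus
#' one particle line in the input column order; velocity columns are written
#' as zeros. Numbers use fixed decimal notation.
#'
#' @param traj An `oxdna_traj`, or a single `oxdna_conf`.
#' @param path Output path.
#' @param precision Decimal digits (default 8).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, precision = 8) {
  if (inherits(traj, "oxdna_conf"))
    traj <- structure(list(topology = NULL, frames = list(traj),
                           n_frames = 1L), class = "oxdna_traj")
  con <- file(path, "wb")
  on.exit(close(con))
  for (k in seq_len(traj$n_frames))
    writeLines(.fmt_conf(get_frame(traj, k), precision), con, sep = "\n")
  invisible(path)
}

#' Read a space-separated index file
#'
#' Index files hold 0-based nucleotide ids, e.g. a selection exported from
#' the viewer. Order is preserved; duplicates are rejected.
#'
#' @param path Path to the file.
#' @return Integer vector of 0-based ids.
#' @export
read_index_file <- function(path) {
  txt <- paste(.read_lines(path), collapse = " ")
  ids <- suppressWarnings(as.integer(strsplit(trimws(txt), "\\s+")[[1]]))
  if (anyNA(ids)) .stopf("index file %s: non-integer entry", path)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    .stopf("index file %s: duplicate ids %s", path,
           paste(unique(dup), collapse = ", "))
  ids
}

#' Designed base-pair list
#'
#' The set of base pairs intended by a design, against which simulated
#' bonding is scored. Stored as an unordered pair set: `i != j`, every id
#' appears in at most one pair (an involution).
#'
#' @param i,j Integer vectors of 0-based global ids (paired elementwise).
#' @return Object of class `designed_pairs`: a 2-column integer matrix with
#'   `min(i,j)` in column 1, sorted by column 1.
#' @export
designed_pairs <- function(i = integer(0), j = integer(0)) {
  i <- as.integer(i); j <- as.integer(j)
  if (length(i) != length(j)) .stopf("designed_pairs: i and j lengths differ")
  if (any(i == j)) .stopf("designed_pairs: a nucleotide cannot pair itself")
  m <- cbind(pmin(i, j), pmax(i, j))
  m <- unique(m)
  ids <- c(m[, 1], m[, 2])
  if (anyDuplicated(ids))
    .stopf("designed_pairs: id(s) %s appear in more than one pair",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- m[order(m[, 1]), , drop = FALSE]
  structure(m, class = c("designed_pairs", class(m)))
}

#' Read a designed-pairs file
#'
#' One whitespace-delimited `i j` pair per line (0-based ids).
#'
#' @param path Path to the file.
#' @return A `designed_pairs` object.
#' @export
read_pairs_file <- function(path) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(designed_pairs())
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.integer))
  designed_pairs(m[, 1], m[, 2])
}

#' Write a designed-pairs file
#' @param pairs A `designed_pairs` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_file <- function(pairs, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(pairs))
    writeLines(sprintf("%d %d", pairs[, 1], pairs[, 2]), con, sep = "\n")
  invisible(path)
}

#' Convert designed pairs to mutual traps
#'
#' Emits two reciprocal trap records per pair, suitable for writing as an
#' oxDNA external-forces file that pulls each designed pair together during
#' relaxation.
#'
#' @param pairs A `designed_pairs` object.
#' @param stiffness Spring stiffness (> 0), simulation units.
#' @param r0 Equilibrium trap distance, simulation length units.
#' @return A `mutual_traps` data frame with columns `particle`,
#'   `ref_particle`, `stiff`, `r0`.
#' @export
pairs_to_forces <- function(pairs, stiffness = 0.9, r0 = 1.2) {
  if (stiffness <= 0) .stopf("stiffness must be > 0")
  df <- data.frame(
    particle = as.integer(c(rbind(pairs[, 1], pairs[, 2]))),
    ref_particle = as.integer(c(rbind(pairs[, 2], pairs[, 1]))),
    stiff = rep(stiffness, 2L * nrow(pairs)),
    r0 = rep(r0, 2L * nrow(pairs))
  )
  structure(df, class = c("mutual_traps", "data.frame"))
}

#' Convert mutual traps back to designed pairs
#'
#' @param traps A `mutual_traps` data frame; every trap must have a
#'   reciprocal partner.
#' @return A `designed_pairs` object.
#' @export
forces_to_pairs <- function(traps) {
  if (nrow(traps) == 0L) return(designed_pairs())
  key <- paste(pmin(traps$particle, traps$ref_particle),
               pmax(traps$particle, traps$ref_particle))
  cnt <- table(key)
  orphans <- names(cnt)[cnt != 2L]
  if (length(orphans))
    .stopf("unpaired trap(s) without a reciprocal partner: %s",
           paste(orphans, collapse = "; "))
  keep <- !duplicated(key)
  designed_pairs(traps$particle[keep], traps$ref_particle[keep])
}

#' Write an oxDNA external-forces file of mutual traps
#' @param traps A `mutual_traps` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_force_file <- function(traps, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (r in seq_len(nrow(traps))) {
    writeLines(c("{", "type = mutual_trap",
                 sprintf("particle = %d", traps$particle[r]),
                 sprintf("ref_particle = %d", traps$ref_particle[r]),
                 sprintf("stiff = %g", traps$stiff[r]),
                 sprintf("r0 = %g", traps$r0[r]),
                 "}", ""), con, sep = "\n")
  }
  invisible(path)
}

#' Read an oxDNA external-forces file of mutual traps
#' @param path Path to the file.
#' @return A `mutual_traps` data frame.
#' @export
read_force_file <- function(path) {
  lines <- trimws(.read_lines(path))
  kv <- grep("=", lines, value = TRUE)
  keys <- trimws(sub("=.*", "", kv))
  vals <- trimws(sub("^[^=]*=", "", kv))
  pick <- function(k) vals[keys == k]
  types <- pick("type")
  if (any(types != "mutual_trap"))
    .stopf("%s: only mutual_trap forces are supported", path)
  df <- data.frame(particle = as.integer(pick("particle")),
                   ref_particle = as.integer(pick("ref_particle")),
                   stiff = as.numeric(pick("stiff")),
                   r0 = as.numeric(pick("r0")))
  structure(df, class = c("mutual_traps", "data.frame"))
}

# ---- viewer overlays --------------------------------------------------------

#' Viewer data overlays
#'
#' Three JSON overlay kinds are understood by the viewer: a colour overlay
#' (one scalar per particle, rendered as a colormap on the structure), a
#' vector overlay (a 3-vector per particle, drawn as an arrow from each
#' particle) and a free arrow overlay (any number of origin/direction pairs).
#'
#' @param name Overlay label (the JSON key).
#' @param values Numeric vector, one value per particle.
#' @return An object of class `color_overlay` / `vector_overlay` /
#'   `arrow_overlay`.
#' @export
color_overlay <- function(name, values) {
  structure(list(name = name, values = as.numeric(values)),
            class = "color_overlay")
}

#' @rdname color_overlay
#' @param vectors N x 3 numeric matrix, one 3-vector per particle.
#' @export
vector_overlay <- function(name, vectors) {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != 3L) .stopf("vector overlay needs an N x 3 matrix")
  structure(list(name = name, vectors = vectors), class = "vector_overlay")
}

#' @rdname color_overlay
#' @param origins,directions M x 3 matrices describing M free arrows.
#' @export
arrow_overlay <- function(name, origins, directions) {
  origins <- as.matrix(origins); directions <- as.matrix(directions)
  if (!all(dim(origins) == dim(directions)) || ncol(origins) != 3L)
    .stopf("arrow overlay needs matching M x 3 origin/direction matrices")
  if (!all(is.finite(origins)) || !all(is.finite(directions)))
    .stopf("arrow overlay: non-finite components")
  structure(list(name = name, origins = origins, directions = directions),
            class = "arrow_overlay")
}

#' Write a viewer overlay JSON file
#'
#' The file is a JSON object mapping the overlay name to a flat numeric
#' array: one scalar per particle (colour), three floats per particle
#' (vector) or six floats per arrow (origin then direction). Values are
#' rounded to 6 significant digits; overlay precision is visual only.
#'
#' @param overlay A `color_overlay`, `vector_overlay` or `arrow_overlay`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(overlay, path) {
  flat <- if (inherits(overlay, "color_overlay")) overlay$values
    else if (inherits(overlay, "vector_overlay")) as.vector(t(overlay$vectors))
    else if (inherits(overlay, "arrow_overlay"))
      as.vector(t(cbind(overlay$origins, overlay$directions)))
    else .stopf("not an overlay object")
  obj <- stats::setNames(list(signif(flat, 6)), overlay$name)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a viewer overlay JSON file
#'
#' @param path Path to the JSON file.
#' @param kind One of "color", "vector", "arrow"; how to reshape the flat
#'   value array.
#' @return The corresponding overlay object.
#' @export
read_overlay <- function(path, kind = c("color", "vector", "arrow")) {
  kind <- match.arg(kind)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(obj) != 1L) .stopf("%s: expected a single-key overlay", path)
  name <- names(obj)
  flat <- as.numeric(obj[[1]])
  switch(kind,
    color = color_overlay(name, flat),
    vector = {
      if (length(flat) %% 3L) .stopf("%s: length not divisible by 3", path)
      vector_overlay(name, matrix(flat, ncol = 3L, byrow = TRUE))
    },
    arrow = {
      if (length(flat) %% 6L) .stopf("%s: length not divisible by 6", path)
      m <- matrix(flat, ncol = 6L, byrow = TRUE)
      arrow_overlay(name, m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE])
    })
}

#' Export strand sequences as CSV
#'
#' One row per strand: strand id, length, sequence in 5' to 3' order (the
#' synthesis-order convention used on oligo ordering forms) and a circular
#' flag. Circular strand sequences start at the member with the lowest
#' global id.
#'
#' @param topo An `oxdna_topology`.
#' @param path Output path.
#' @return The data frame written, invisibly.
#' @export
export_sequences_csv <- function(topo, path) {
  rows <- lapply(seq_along(topo$strand_ids), function(k) {
    sid <- topo$strand_ids[k]
    s <- strand_sequence(topo, sid)
    data.frame(strand = sid, length = length(s),
               sequence = paste(s, collapse = ""),
               circular = unname(topo$circular[as.character(sid)]))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
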