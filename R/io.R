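# Structure/trajectory I/O: multi-frame GRO, XYZ and PDB.
# Coordinates are angstrom internally; GRO files are nm at the boundary.
# TIP4P/2005 M-site positions are always rederived from the atomic sites on
# input (never trusted from file) and emitted on output.

## site-name -> atom-type mapping for the shipped templates
.guess_type <- function(site, resname) {
  key <- toupper(site)
  res <- toupper(resname)
  if (res == "SOL") {
    if (key == "OW") return("O_w")
    if (key %in% c("HW1", "HW2")) return("H_w")
    if (key == "MW") return("M_w")
  }
  if (res == "OHX") {
    if (startsWith(key, "O")) return("O_oh")
    if (startsWith(key, "H")) return("H_oh")
  }
  if (res %in% c("LI", "NA", "K"))
    return(c(LI = "Li", `NA` = "Na", K = "K")[[res]])
  site  # unknown species keep their site name as type label
}

.apply_msites <- function(config) {
  if (any(config$type == "M_w")) .derive_msites(config) else config
}

#' Write a configuration or trajectory to a GRO file
#'
#' Multi-frame GROMACS .gro (fixed width, coordinates in nm with 3
#' decimals). Residue and atom numbers wrap at the format limits.
#'
#' @param x An `"md_config"` or `"md_traj"`.
#' @param path Output file.
#' @param title Title line (a provenance comment).
#' @return `path`, invisibly.
#' @export
write_gro <- function(x, path, title = "written by hydroxff") {
  traj <- .as_traj(x)
  con <- file(path, "w"); on.exit(close(con))
  for (f in traj$frames) {
    n <- nrow(f$xyz)
    writeLines(title, con)
    writeLines(sprintf("%5d", n), con)
    resid <- f$mol_id %% 100000L
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     resid, substr(f$mol_name, 1, 5), substr(f$site, 1, 5),
                     seq_len(n) %% 100000L,
                     f$xyz[, 1] / 10, f$xyz[, 2] / 10, f$xyz[, 3] / 10)
    writeLines(lines, con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", f$box[1] / 10, f$box[2] / 10, f$box[3] / 10), con)
  }
  invisible(path)
}

#' Read a (multi-frame) GRO file
#'
#' @param path Input file.
#' @return An `"md_traj"` (single-frame files give a 1-frame trajectory).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list(); i <- 1L; k <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    k <- k + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n) || i + 1L + n + 1L > length(lines))
      .stopf("malformed GRO frame %d (bad atom count at line %d)", k, i + 1L)
    at <- lines[(i + 2L):(i + 1L + n)]
    resid <- suppressWarnings(as.integer(substr(at, 1, 5)))
    resname <- trimws(substr(at, 6, 10))
    site <- trimws(substr(at, 11, 15))
    xyz <- 10 * cbind(as.numeric(substr(at, 21, 28)),
                      as.numeric(substr(at, 29, 36)),
                      as.numeric(substr(at, 37, 44)))
    if (any(is.na(xyz)) || any(is.na(resid)))
      .stopf("malformed GRO frame %d (unparsable atom record)", k)
    boxline <- as.numeric(strsplit(trimws(lines[i + 1L + n + 1L]), "\\s+")[[1]])
    if (length(boxline) < 3L || any(is.na(boxline[1:3])))
      .stopf("malformed GRO frame %d (bad box line)", k)
    mol_id <- cumsum(c(1L, diff(resid) != 0L | resname[-1L] != resname[-n]))
    type <- mapply(.guess_type, site, resname, USE.NAMES = FALSE)
    cfg <- md_config(boxline[1:3] * 10, xyz, site, type, mol_id, resname)
    frames[[k]] <- .apply_msites(cfg)
    i <- i + 1L + n + 2L
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (!length(frames)) .stopf("no frames found in '%s'", path)
  md_traj(frames)
}

#' Write a configuration or trajectory to an XYZ file
#'
#' Coordinates in angstrom, `%.6f`. The comment line carries the box and an
#' optional provenance note, as `box = lx ly lz`.
#'
#' @inheritParams write_gro
#' @param comment Extra text appended to the comment line of every frame.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, comment = "") {
  traj <- .as_traj(x)
  con <- file(path, "w"); on.exit(close(con))
  for (f in traj$frames) {
    writeLines(sprintf("%d", nrow(f$xyz)), con)
    writeLines(trimws(sprintf("box = %.6f %.6f %.6f %s",
                              f$box[1], f$box[2], f$box[3], comment)), con)
    writeLines(sprintf("%-5s %12.6f %12.6f %12.6f",
                       f$site, f$xyz[, 1], f$xyz[, 2], f$xyz[, 3]), con)
  }
  invisible(path)
}

#' Read a (multi-frame) XYZ file
#'
#' The comment line is scanned for `box = lx ly lz` (or three bare numbers);
#' frames without a parsable box get `fallback_box`. XYZ carries no
#' molecule topology: every site becomes its own molecule and its name is
#' used as the atom-type label.
#'
#' @param path Input file.
#' @param fallback_box Box to use when the comment line has none.
#' @return An `"md_traj"`.
#' @export
read_xyz <- function(path, fallback_box = NULL) {
  lines <- readLines(path)
  frames <- list(); i <- 1L; k <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    k <- k + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || i + 1L + n > length(lines))
      .stopf("malformed XYZ frame %d (bad atom count at line %d)", k, i)
    nums <- regmatches(lines[i + 1L],
                       gregexpr("[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?", lines[i + 1L]))[[1]]
    box <- if (length(nums) >= 3) as.numeric(nums[1:3]) else fallback_box
    if (is.null(box)) .stopf("XYZ frame %d has no box in its comment line and no fallback_box", k)
    at <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    bad <- which(vapply(at, length, 0L) < 4L)
    if (length(bad)) .stopf("malformed XYZ frame %d (atom record %d)", k, bad[1])
    site <- vapply(at, `[[`, "", 1L)
    xyz <- t(vapply(at, function(v) as.numeric(v[2:4]), numeric(3)))
    if (any(is.na(xyz))) .stopf("malformed XYZ frame %d (non-numeric coordinate)", k)
    frames[[k]] <- md_config(box, xyz, site, site, seq_len(n), site)
    i <- i + 2L + n
  }
  if (!length(frames)) .stopf("no frames found in '%s'", path)
  md_traj(frames)
}

## hybrid-36 encoding for PDB fixed-width numbers past their decimal limit
.hy36 <- function(v, width) {
  dec_limit <- 10^width - 1
  enc1 <- function(x) {
    if (x <= dec_limit) return(formatC(x, width = width))
    digits36 <- c(0:9, LETTERS)
    x2 <- x - dec_limit - 1 + 10 * 36^(width - 1)
    if (x2 >= 36^width) .stopf("number %d exceeds hybrid-36 width-%d upper range", x, width)
    out <- character(width)
    for (p in width:1) { out[p] <- digits36[x2 %% 36 + 1]; x2 <- x2 %/% 36 }
    paste(out, collapse = "")
  }
  vapply(as.integer(v), enc1, "")
}

#' Write a configuration or trajectory to a PDB file
#'
#' Multi-frame output uses MODEL/ENDMDL records and a CRYST1 box. Residue
#' and atom serial numbers beyond the fixed-width decimal limits use
#' hybrid-36 encoding, so systems with more than 9999 residues are written
#' without truncation.
#'
#' @inheritParams write_gro
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path, title = "written by hydroxff") {
  traj <- .as_traj(x)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("TITLE     %s", title), con)
  multi <- length(traj$frames) > 1L
  for (fr in seq_along(traj$frames)) {
    f <- traj$frames[[fr]]
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       f$box[1], f$box[2], f$box[3]), con)
    if (multi) writeLines(sprintf("MODEL %8d", fr), con)
    n <- nrow(f$xyz)
    ## cols: serial 7-11, name 13-16, altLoc 17, resName 18-21, chain 22,
    ## resSeq 23-26, coords 31-54
    lines <- sprintf("ATOM  %s %-4s %-4s%1s%s    %8.3f%8.3f%8.3f  1.00  0.00",
                     .hy36(seq_len(n), 5L), substr(f$site, 1, 4),
                     substr(f$mol_name, 1, 4), "", .hy36(f$mol_id, 4L),
                     f$xyz[, 1], f$xyz[, 2], f$xyz[, 3])
    writeLines(lines, con)
    writeLines(if (multi) "ENDMDL" else "END", con)
  }
  invisible(path)
}

.hy36_decode <- function(s, width) {
  s <- trimws(s)
  dec <- suppressWarnings(as.integer(s))
  idx <- which(is.na(dec))
  for (i in idx) {
    v <- strtoi(s[i], base = 36L)
    if (is.na(v)) .stopf("unparsable hybrid-36 field '%s'", s[i])
    dec[i] <- v - 10 * 36^(width - 1) + 10^width
  }
  dec
}

#' Read a (multi-frame) PDB file
#'
#' Understands ATOM/HETATM, CRYST1 and MODEL/ENDMDL records, with hybrid-36
#' serial and residue numbers.
#'
#' @param path Input file.
#' @param fallback_box Box (A) used when no CRYST1 record is present.
#' @return An `"md_traj"`.
#' @export
read_pdb <- function(path, fallback_box = NULL) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  box <- fallback_box
  frames <- list(); cur <- character(0); k <- 0L
  flush <- function(cur, box, k) {
    if (!length(cur)) return(NULL)
    if (is.null(box)) .stopf("PDB frame %d has no CRYST1 record and no fallback_box", k)
    site <- trimws(substr(cur, 13, 16))
    resname <- trimws(substr(cur, 18, 21))
    resid <- .hy36_decode(substr(cur, 23, 26), 4L)
    xyz <- cbind(as.numeric(substr(cur, 31, 38)),
                 as.numeric(substr(cur, 39, 46)),
                 as.numeric(substr(cur, 47, 54)))
    if (any(is.na(xyz))) .stopf("malformed PDB frame %d (bad coordinates)", k)
    n <- length(site)
    mol_id <- cumsum(c(1L, diff(resid) != 0L | resname[-1L] != resname[-n]))
    type <- mapply(.guess_type, site, resname, USE.NAMES = FALSE)
    .apply_msites(md_config(box, xyz, site, type, mol_id, resname))
  }
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (r == "CRYST1") {
      box <- as.numeric(c(substr(lines[i], 7, 15), substr(lines[i], 16, 24),
                          substr(lines[i], 25, 33)))
    } else if (r %in% c("ATOM  ", "HETATM")) {
      cur <- c(cur, lines[i])
    } else if (r %in% c("ENDMDL", "END   ") || (r == "END" && nchar(trimws(lines[i])) == 3)) {
      k <- k + 1L
      f <- flush(cur, box, k)
      if (!is.null(f)) frames[[length(frames) + 1L]] <- f
      cur <- character(0)
    }
  }
  if (length(cur)) { k <- k + 1L; frames[[length(frames) + 1L]] <- flush(cur, box, k) }
  if (!length(frames)) .stopf("no frames found in '%s'", path)
  md_traj(frames)
}
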