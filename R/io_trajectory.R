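# Trajectory file I/O.
#
# Two plain-text formats: multi-model PDB (one bead = one pseudo-atom
# record, chain IDs A/B for the solute and S for solvent; internal nm
# converted to the standard 3-decimal Angstrom fields at the boundary)
# and a whitespace-delimited XYZ-per-frame format that stays in nm.
# Reading PDB goes through bio3d after a light structural validation
# that yields line-numbered errors; the multi-model writer is local
# because bio3d only writes single models.

NM_PER_ANGSTROM <- 0.1

#' Write a multi-model PDB trajectory
#'
#' @param frames list of n x 3 coordinate matrices, nm.
#' @param file output path.
#' @param chain chain ID per bead (default all "A").
#' @param labels residue-name label per bead (3 characters used).
#' @param elety atom-name per bead (default "CA", "OW" for solvent
#'   chain "S").
#' @return the file path, invisibly.
#' @export
write_trajectory_pdb <- function(frames, file, chain = NULL,
                                 labels = NULL, elety = NULL) {
  stopifnot(length(frames) >= 1L)
  n <- nrow(frames[[1]])
  if (is.null(chain)) chain <- rep("A", n)
  if (is.null(labels)) labels <- rep("BEA", n)
  if (is.null(elety)) elety <- ifelse(chain == "S", "OW", "CA")
  labels <- sprintf("%-3s", substr(labels, 1, 3))
  con <- file(file, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    x <- frames[[k]]
    if (nrow(x) != n)
      stop("frame ", k, " has ", nrow(x), " beads, expected ", n)
    writeLines(sprintf("MODEL     %4d", k), con)
    a <- x / NM_PER_ANGSTROM
    writeLines(sprintf(
      "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(n), elety, "", labels, chain, seq_len(n), "",
      a[, 1], a[, 2], a[, 3], 1, 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Read a multi-model PDB trajectory
#'
#' Validates the MODEL/ENDMDL structure first (errors name the
#' offending line), then parses through \code{bio3d::read.pdb}.
#'
#' @param file path to a multi-model PDB file.
#' @return list: \code{frames} (list of n x 3 matrices, nm),
#'   \code{chain}, \code{labels} (residue names), \code{elety}.
#' @export
read_trajectory_pdb <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  lines <- readLines(file)
  model_at <- grep("^MODEL", lines)
  endmdl_at <- grep("^ENDMDL", lines)
  if (length(model_at) == 0L)
    stop("no MODEL records in ", file)
  if (length(endmdl_at) < length(model_at))
    stop("truncated trajectory: MODEL at line ",
         model_at[length(model_at)], " has no matching ENDMDL")
  counts <- vapply(seq_along(model_at), function(k)
    sum(grepl("^ATOM", lines[model_at[k]:endmdl_at[k]])), 0L)
  if (length(unique(counts)) > 1L)
    stop("inconsistent atom count across models (MODEL at line ",
         model_at[which(counts != counts[1])[1]], " has ",
         counts[counts != counts[1]][1], " atoms, expected ",
         counts[1], ")")
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  nfr <- nrow(pdb$xyz)
  frames <- lapply(seq_len(nfr), function(k)
    matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE) * NM_PER_ANGSTROM)
  list(frames = frames, chain = pdb$atom$chain,
       labels = trimws(pdb$atom$resid), elety = trimws(pdb$atom$elety))
}

#' Write an XYZ-per-frame trajectory
#'
#' Plain whitespace format in nm: per frame, a bead-count line, a
#' comment line ("frame k"), then one "label x y z" line per bead.
#'
#' @param frames list of n x 3 coordinate matrices, nm.
#' @param file output path.
#' @param labels per-bead labels (default "X").
#' @return the file path, invisibly.
#' @export
write_trajectory_xyz <- function(frames, file, labels = NULL) {
  stopifnot(length(frames) >= 1L)
  n <- nrow(frames[[1]])
  if (is.null(labels)) labels <- rep("X", n)
  con <- file(file, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    x <- frames[[k]]
    if (nrow(x) != n)
      stop("frame ", k, " has ", nrow(x), " beads, expected ", n)
    writeLines(as.character(n), con)
    writeLines(paste("frame", k), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", labels, x[, 1], x[, 2],
                       x[, 3]), con)
  }
  invisible(file)
}

#' Read an XYZ-per-frame trajectory
#'
#' @param file path.
#' @return list: \code{frames} (list of n x 3 matrices, nm),
#'   \code{labels}.
#' @export
read_trajectory_xyz <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  lines <- readLines(file)
  frames <- list(); labels <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop("malformed bead-count record at line ", i)
    n <- as.integer(lines[i])
    if (i + 1L + n > length(lines))
      stop("truncated frame starting at line ", i, ": expected ", n,
           " bead records")
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, 0L) != 4L)
    if (length(bad))
      stop("malformed bead record at line ", i + 1L + bad[1])
    lab <- vapply(parts, `[`, "", 1L)
    xyz <- matrix(suppressWarnings(
      as.numeric(unlist(lapply(parts, `[`, 2:4)))),
      ncol = 3, byrow = TRUE)
    if (anyNA(xyz))
      stop("non-numeric coordinate in frame starting at line ", i)
    if (is.null(labels)) labels <- lab
    else if (!identical(labels, lab))
      stop("inconsistent bead labels in frame starting at line ", i)
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  list(frames = frames, labels = labels)
}

#' Read a trajectory in either supported format
#'
#' @param file path.
#' @param format \code{"pdb"} or \code{"xyz"}; default guessed from
#'   the extension.
#' @return see \code{\link{read_trajectory_pdb}} /
#'   \code{\link{read_trajectory_xyz}}.
#' @export
read_trajectory <- function(file, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", file, ignore.case = TRUE)) "pdb"
              else "xyz"
  if (format == "pdb") read_trajectory_pdb(file)
  else read_trajectory_xyz(file)
}

#' Write a per-frame energy sidecar CSV
#'
#' @param info data frame with at least columns \code{cycle} and
#'   \code{energy} (a \code{baseline_ensemble$info} works as is).
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_energy_sidecar <- function(info, file) {
  write.csv(info, file, row.names = FALSE)
  invisible(file)
}
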