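# Particle pose I/O in the RELION STAR dialect.
#
# The pipeline's canonical internal unit is nm; STAR coordinates are pixels
# (with a mandatory pixel size in Angstrom per pixel, the common convention
# for exported subtomogram-averaging tables) or Angstrom behind a flag.
# A single loop_ data block is read/written; RELION 3.1-style optics blocks
# are skipped: the pipeline needs poses, not CTF metadata.

star_required_cols <- c("rlnCoordinateX", "rlnCoordinateY", "rlnCoordinateZ",
                        "rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi")

# Parse all data blocks of a STAR file into a named list of data frames
# (character columns; callers convert).
parse_star <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", ifelse(grepl("^\\s*#", lines), "", lines))
  lines <- trimws(lines)
  blocks <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (grepl("^data_", lines[i])) {
      block_name <- sub("^data_", "", lines[i])
      i <- i + 1L
      # seek loop_
      while (i <= n && !grepl("^loop_", lines[i]) && !grepl("^data_", lines[i]))
        i <- i + 1L
      if (i > n || grepl("^data_", lines[i])) next
      i <- i + 1L
      cols <- character()
      while (i <= n && grepl("^_", lines[i])) {
        cols <- c(cols, sub("^_(\\S+).*$", "\\1", lines[i]))
        i <- i + 1L
      }
      rows <- list()
      while (i <= n && nzchar(lines[i]) && !grepl("^(data_|loop_)", lines[i])) {
        rows[[length(rows) + 1L]] <- strsplit(lines[i], "\\s+")[[1]]
        i <- i + 1L
      }
      tab <- if (length(rows)) {
        bad <- which(lengths(rows) != length(cols))
        if (length(bad))
          stop(sprintf("STAR block 'data_%s': row %d has %d fields, expected %d",
                       block_name, bad[1], length(rows[[bad[1]]]), length(cols)))
        as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
      } else {
        as.data.frame(matrix(character(), 0, length(cols)),
                      stringsAsFactors = FALSE)
      }
      names(tab) <- cols
      blocks[[block_name]] <- tab
    } else i <- i + 1L
  }
  blocks
}

star_numeric <- function(tab, col) {
  v <- suppressWarnings(as.numeric(tab[[col]]))
  bad <- which(is.na(v) & nzchar(tab[[col]]))
  if (length(bad))
    stop(sprintf("non-numeric value '%s' in column %s at row %d",
                 tab[[col]][bad[1]], col, bad[1]))
  v
}

#' Read a particle pose table from a STAR file
#'
#' Reads a RELION-dialect STAR particle table, converts coordinates to nm
#' and groups particles into cells by tomogram name (`rlnTomoName`, falling
#' back to `rlnMicrographName`; single group when neither is present).
#' Euler angles are passed through as intrinsic ZYZ rot/tilt/psi degrees.
#'
#' @param path Path to the STAR file.
#' @param pixel_size Pixel size in Angstrom per pixel; coordinates are
#'   interpreted as pixels and converted to nm. Ignored when
#'   `angstrom_coords = TRUE`.
#' @param angstrom_coords Logical; treat coordinates as Angstrom instead of
#'   pixels.
#' @param truth_path Optional sidecar TSV of truth labels keyed by
#'   `particle_id` (as written by [write_particles()]); merged back as
#'   `truth_*` columns.
#' @return A [particle_set()].
#' @export
read_particles <- function(path, pixel_size = NULL, angstrom_coords = FALSE,
                           truth_path = NULL) {
  if (!angstrom_coords && is.null(pixel_size))
    stop("pixel_size (Angstrom per pixel) is required unless angstrom_coords = TRUE")
  blocks <- parse_star(path)
  if (!length(blocks)) stop("no data block found in ", path)
  has_cols <- vapply(blocks, function(b) all(star_required_cols %in% names(b)),
                     logical(1))
  if (!any(has_cols)) {
    missing <- setdiff(star_required_cols, names(blocks[[length(blocks)]]))
    stop("missing required STAR column(s): ", paste(missing, collapse = ", "))
  }
  tab <- blocks[[which(has_cols)[1]]]
  to_nm <- if (angstrom_coords) 0.1 else pixel_size / 10
  pos <- cbind(star_numeric(tab, "rlnCoordinateX"),
               star_numeric(tab, "rlnCoordinateY"),
               star_numeric(tab, "rlnCoordinateZ")) * to_nm
  eul <- cbind(star_numeric(tab, "rlnAngleRot"),
               star_numeric(tab, "rlnAngleTilt"),
               star_numeric(tab, "rlnAnglePsi"))
  cell <- if ("rlnTomoName" %in% names(tab)) tab$rlnTomoName
          else if ("rlnMicrographName" %in% names(tab)) tab$rlnMicrographName
          else rep("cell_001", nrow(tab))
  ids <- if ("rlnTomoParticleId" %in% names(tab))
    as.integer(star_numeric(tab, "rlnTomoParticleId"))
  else seq_len(nrow(tab))
  out <- particle_set(ids, cell, pos, eul)
  if (!is.null(truth_path)) {
    truth <- utils::read.delim(truth_path, check.names = FALSE)
    if (!"particle_id" %in% names(truth))
      stop("truth sidecar must carry a particle_id column")
    m <- match(out$particle_id, truth$particle_id)
    for (cn in setdiff(names(truth), "particle_id")) {
      col <- paste0(ifelse(startsWith(cn, "truth_"), "", "truth_"), cn)
      out[[col]] <- truth[[cn]][m]
    }
  }
  out
}

#' Write a particle pose table to a STAR file
#'
#' Writes a single `data_particles` block with a fixed column order
#' (particle id, tomogram name, coordinates, Euler angles). Coordinates
#' are converted from nm to pixels (or Angstrom) and formatted with six
#' decimal places; rot/psi angles are canonicalised to [-180, 180).
#'
#' @param particles A [particle_set()].
#' @param path Output path.
#' @param pixel_size Pixel size in Angstrom per pixel for the coordinate
#'   conversion (ignored when `angstrom_coords = TRUE`).
#' @param angstrom_coords Logical; write coordinates in Angstrom.
#' @param truth_path Optional path for a sidecar TSV holding the set's
#'   `truth_*` columns keyed by `particle_id`.
#' @return `path`, invisibly.
#' @export
write_particles <- function(particles, path, pixel_size = NULL,
                            angstrom_coords = FALSE, truth_path = NULL) {
  assert_particle_set(particles)
  if (!angstrom_coords && is.null(pixel_size))
    stop("pixel_size (Angstrom per pixel) is required unless angstrom_coords = TRUE")
  from_nm <- if (angstrom_coords) 10 else 10 / pixel_size
  cols <- c("rlnTomoParticleId", "rlnTomoName",
            "rlnCoordinateX", "rlnCoordinateY", "rlnCoordinateZ",
            "rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi")
  header <- c("", "data_particles", "", "loop_",
              sprintf("_%s #%d", cols, seq_along(cols)))
  fmt <- function(x) sprintf("%.6f", x)
  rows <- if (nrow(particles)) {
    paste(particles$particle_id, particles$cell_id,
          fmt(particles$x * from_nm), fmt(particles$y * from_nm),
          fmt(particles$z * from_nm),
          fmt(wrap180(particles$rot)), fmt(particles$tilt),
          fmt(wrap180(particles$psi)))
  } else character()
  writeLines(c(header, rows, ""), path)
  truth_cols <- grep("^truth_", names(particles), value = TRUE)
  if (!is.null(truth_path) && length(truth_cols)) {
    utils::write.table(
      as.data.frame(particles[, c("particle_id", truth_cols)]),
      truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
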