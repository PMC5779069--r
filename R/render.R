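## Renderable-geometry export: the overall morphology as connected external
## frustums, the secondary signal as internal frustums whose cross-section
## encodes the above-threshold voxel fraction, with mean intensity mapped to
## a colour ramp.

## Triangulated frustum between two circles; returns list(vertices, faces)
## with faces 1-based into vertices. Degenerate to a point at radius 0.
.frustumMesh <- function(p0, r0, p1, r1, nseg = 12L) {
  axis <- p1 - p0
  L <- sqrt(sum(axis^2))
  if (L == 0) {
    axis <- c(0, 0, 1)
    L <- 1
  }
  u <- axis / L
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    u[2] * e1[3] - u[3] * e1[2],
    u[3] * e1[1] - u[1] * e1[3],
    u[1] * e1[2] - u[2] * e1[1]
  )
  th <- 2 * pi * (seq_len(nseg) - 1) / nseg
  ring <- function(p, r) {
    t(vapply(th, function(a) p + r * (cos(a) * e1 + sin(a) * e2), numeric(3)))
  }
  v <- rbind(ring(p0, r0), ring(p1, r1))
  f <- NULL
  for (s in seq_len(nseg)) {
    sn <- s %% nseg + 1L
    f <- rbind(
      f,
      c(s, sn, nseg + sn),
      c(s, nseg + sn, nseg + s)
    )
  }
  list(vertices = v, faces = f)
}

#' Export renderable frustum geometry (OBJ + colour table)
#'
#' Writes the overall morphology as translucent external frustums and, for
#' every compartment whose ratio is positive, an internal frustum whose
#' radius is the external radius scaled by sqrt(ratio), so that the internal
#' cross-sectional area fraction approximates the volumetric voxel fraction.
#' Each internal frustum's colour is the mean intensity mapped linearly onto
#' a indigo-to-dark-red ramp over `colorLimits` and clamped at the ends
#' (means at or below the lower limit take the low-end colour, at or above
#' the upper limit the high-end colour).
#'
#' @param x an [EswcSet-class].
#' @param path output OBJ file path; the colour table is written next to it
#'   as `<path>.colors.csv`.
#' @param colorLimits numeric (low, high) intensity limits of the ramp;
#'   low < high required.
#' @param channel which channel to render (index into `eswcChannels(x)`).
#' @param nseg circle tessellation segments per frustum ring.
#' @return Invisibly, a data.frame describing every exported object
#'   (object name, kind external/internal, node id, mean, ratio, colour hex).
#' @export
renderOBJ <- function(x, path, colorLimits = c(15, 100), channel = 1L, nseg = 12L) {
  if (colorLimits[1] >= colorLimits[2]) stop("colorLimits must satisfy low < high")
  comps <- compartments(x@tree)
  C <- length(x@channels)
  if (C > 0 && (channel < 1L || channel > C)) stop("channel out of range")
  ramp <- grDevices::colorRamp(c("#4B0082", "#8B0000"))
  colorOf <- function(mean) {
    f <- (mean - colorLimits[1]) / (colorLimits[2] - colorLimits[1])
    f <- min(1, max(0, f))
    grDevices::rgb(ramp(f)[1], ramp(f)[2], ramp(f)[3], maxColorValue = 255)
  }
  objLines <- character()
  vcount <- 0L
  meta <- list()
  emit <- function(name, mesh) {
    objLines <<- c(
      objLines, sprintf("o %s", name),
      sprintf("v %.6f %.6f %.6f", mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]),
      sprintf("f %d %d %d", mesh$faces[, 1] + vcount, mesh$faces[, 2] + vcount, mesh$faces[, 3] + vcount)
    )
    vcount <<- vcount + nrow(mesh$vertices)
  }
  for (r in seq_len(nrow(comps))) {
    cp <- comps[r, ]
    p0 <- c(cp$px, cp$py, cp$pz)
    p1 <- c(cp$cx, cp$cy, cp$cz)
    r0 <- if (cp$sphere) cp$cr else cp$pr
    mesh <- .frustumMesh(p0 - if (cp$sphere) c(0, 0, cp$cr) else 0, r0,
      p1 + if (cp$sphere) c(0, 0, cp$cr) else 0, cp$cr,
      nseg = nseg
    )
    name <- sprintf("external_%d", cp$id)
    emit(name, mesh)
    meta[[length(meta) + 1L]] <- data.frame(
      object = name, kind = "external", node = cp$id,
      mean = NA_real_, ratio = NA_real_, color = NA_character_
    )
    if (C > 0) {
      ratio <- x@stats[r, 3L * channel - 2L]
      mn <- x@stats[r, 3L * channel - 1L]
      if (ratio > 0) {
        sc <- sqrt(ratio)
        imesh <- .frustumMesh(p0 - if (cp$sphere) c(0, 0, cp$cr * sc) else 0, r0 * sc,
          p1 + if (cp$sphere) c(0, 0, cp$cr * sc) else 0, cp$cr * sc,
          nseg = nseg
        )
        iname <- sprintf("internal_%d", cp$id)
        emit(iname, imesh)
        meta[[length(meta) + 1L]] <- data.frame(
          object = iname, kind = "internal", node = cp$id,
          mean = mn, ratio = ratio, color = colorOf(mn)
        )
      }
    }
  }
  writeLines(c("# frustum geometry export", objLines), path, useBytes = TRUE)
  meta <- do.call(rbind, meta)
  utils::write.csv(meta, paste0(path, ".colors.csv"), row.names = FALSE)
  invisible(meta)
}

## ---- TIFF stack I/O -------------------------------------------------------

#' Read a multi-page TIFF as an ImageStack
#'
#' Pages are z-slices; pixel rows are the image y axis and columns the x
#' axis. Intensities are read as stored integers (no rescaling). Physical
#' spacing is supplied by the caller (micrometres per voxel); TIFF files do
#' not reliably carry z spacing.
#'
#' @param path TIFF file path.
#' @param spacing numeric length-3 (sx, sy, sz) in um/voxel.
#' @return An [ImageStack-class].
#' @export
readTIFFStack <- function(path, spacing = c(1, 1, 1)) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- if (max(vapply(pages, max, numeric(1)), 0) > 255) 16L else 8L
  nz <- length(pages)
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  vox <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) vox[, , k] <- t(pages[[k]])
  ImageStack(vox, spacing = spacing, bitDepth = bits)
}

#' Write an ImageStack as a multi-page TIFF
#'
#' @param stack an [ImageStack-class].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeTIFFStack <- function(stack, path) {
  vmax <- stackMaxIntensity(stack)
  pages <- lapply(seq_len(dim(stack@voxels)[3]), function(k) {
    t(stack@voxels[, , k]) / vmax
  })
  tiff::writeTIFF(pages, path, bits.per.sample = stack@bitDepth)
  invisible(path)
}
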