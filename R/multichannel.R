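## Multi-channel signal extraction: voxel-to-compartment assignment over the
## frustum model, per-compartment (ratio, mean, sd) statistics, and the ESWC /
## back-compatible #CHANNELSWC file dialects.

#' Construct an ImageStack
#'
#' @param voxels 3-D numeric array of integer intensities (nx x ny x nz).
#' @param spacing numeric length-3, micrometres per voxel along x, y, z.
#' @param bitDepth 8 or 16.
#' @return An [ImageStack-class].
#' @export
ImageStack <- function(voxels, spacing = c(1, 1, 1), bitDepth = 8L) {
  new("ImageStack",
    voxels = voxels, spacing = as.numeric(spacing),
    bitDepth = as.integer(bitDepth)
  )
}

#' @describeIn ImageStack Voxel array accessor.
#' @param stack an ImageStack.
#' @export
stackVoxels <- function(stack) stack@voxels

#' @describeIn ImageStack Voxel-count dimensions (nx, ny, nz).
#' @export
stackDims <- function(stack) dim(stack@voxels)

#' @describeIn ImageStack Physical spacing accessor (um/voxel).
#' @export
stackSpacing <- function(stack) stack@spacing

#' @describeIn ImageStack Largest representable intensity (255 or 65535).
#' @export
stackMaxIntensity <- function(stack) if (stack@bitDepth == 16L) 65535 else 255

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf(
    "ImageStack: %d x %d x %d voxels, spacing (%s) um, %d-bit\n",
    d[1], d[2], d[3], paste(.fmtNum(object@spacing), collapse = ", "),
    object@bitDepth
  ))
})

#' Construct an ExtractionConfig
#'
#' @param primaryThreshold intensity threshold on the primary channel;
#'   default 15 on the 0-255 scale (a voxel at exactly the threshold is
#'   considered).
#' @param secondaryThresholds per-secondary-channel thresholds; defaults to
#'   the primary threshold for every channel.
#' @return An [ExtractionConfig-class].
#' @export
ExtractionConfig <- function(primaryThreshold = 15, secondaryThresholds = numeric()) {
  new("ExtractionConfig",
    primaryThreshold = as.numeric(primaryThreshold),
    secondaryThresholds = as.numeric(secondaryThresholds)
  )
}

setMethod("show", "ExtractionConfig", function(object) {
  cat(sprintf(
    "ExtractionConfig: primary threshold %s%s\n",
    .fmtNum(object@primaryThreshold),
    if (length(object@secondaryThresholds)) {
      sprintf(
        ", secondary thresholds (%s)",
        paste(.fmtNum(object@secondaryThresholds), collapse = ", ")
      )
    } else {
      ""
    }
  ))
})

#' Physical centre of a voxel
#'
#' Voxel indices are 0-based; the physical position of voxel (i, j, k) is the
#' centre of its cell, ((i + 0.5) sx, (j + 0.5) sy, (k + 0.5) sz)
#' micrometres, in the same frame as SWC coordinates (no axis flips).
#'
#' @param index integer vector (i, j, k), or a matrix with one ijk row per
#'   voxel.
#' @param spacing numeric length-3 spacing in um/voxel.
#' @param dims optional (nx, ny, nz); when given, out-of-range indices error.
#' @return Numeric vector (or matrix) of physical coordinates in um.
#' @examples
#' voxelCenter(c(0, 0, 0), c(1, 1, 2)) # 0.5 0.5 1.0
#' @export
voxelCenter <- function(index, spacing, dims = NULL) {
  m <- if (is.matrix(index)) index else matrix(index, nrow = 1)
  if (!is.null(dims)) {
    if (any(m < 0) || any(sweep(m, 2, dims, ">="))) {
      stop("voxel index out of range")
    }
  }
  out <- sweep(m + 0.5, 2, spacing, "*")
  if (is.matrix(index)) out else drop(out)
}

## Membership test of points against one compartment row (as produced by
## compartments()). Returns list(inside, ndist): ndist is the radial distance
## normalised by the local radius r(t), the tie-breaking quantity.
.containsPoints <- function(comp, pts) {
  if (comp$sphere) {
    d2 <- (pts[, 1] - comp$cx)^2 + (pts[, 2] - comp$cy)^2 + (pts[, 3] - comp$cz)^2
    nd <- sqrt(d2) / comp$cr
    return(list(inside = nd <= 1, ndist = nd))
  }
  ax <- comp$cx - comp$px
  ay <- comp$cy - comp$py
  az <- comp$cz - comp$pz
  L2 <- ax * ax + ay * ay + az * az
  t <- ((pts[, 1] - comp$px) * ax + (pts[, 2] - comp$py) * ay +
    (pts[, 3] - comp$pz) * az) / L2
  qx <- comp$px + t * ax
  qy <- comp$py + t * ay
  qz <- comp$pz + t * az
  d <- sqrt((pts[, 1] - qx)^2 + (pts[, 2] - qy)^2 + (pts[, 3] - qz)^2)
  rt <- comp$pr + t * (comp$cr - comp$pr)
  nd <- d / rt
  list(inside = t >= 0 & t <= 1 & d <= rt, ndist = nd)
}

#' Test whether a point lies inside a compartment
#'
#' For a frustum, the point is projected onto the parent-to-node axis at
#' parameter t; it is inside iff 0 <= t <= 1 and its radial distance d does
#' not exceed the linearly interpolated radius
#' r(t) = r_parent + t (r_node - r_parent). For a sphere, inside iff the
#' distance to the centre is at most the radius. The normalised radial
#' distance d / r(t) (or dist/radius) is returned for overlap tie-breaking.
#'
#' @param comp one row of [compartments()].
#' @param point numeric length-3 physical point (um), or a matrix of points.
#' @return list with `inside` (logical) and `ndist` (numeric), one entry per
#'   point.
#' @export
compartmentContains <- function(comp, point) {
  pts <- if (is.matrix(point)) point else matrix(point, nrow = 1)
  res <- .containsPoints(comp, pts)
  if (!is.matrix(point)) {
    res$inside <- res$inside[1]
    res$ndist <- res$ndist[1]
  }
  res
}

## Index ranges of voxels whose centres may fall inside a compartment.
.compBBox <- function(comp, spacing, dims) {
  r <- max(comp$pr, comp$cr)
  lo <- c(min(comp$px, comp$cx), min(comp$py, comp$cy), min(comp$pz, comp$cz)) - r
  hi <- c(max(comp$px, comp$cx), max(comp$py, comp$cy), max(comp$pz, comp$cz)) + r
  i0 <- pmax(0L, as.integer(floor(lo / spacing - 0.5)))
  i1 <- pmin(dims - 1L, as.integer(ceiling(hi / spacing - 0.5)))
  if (any(i1 < i0)) NULL else cbind(i0, i1)
}

#' Assign image voxels to compartments
#'
#' Implements the voxel-assignment step of multi-channel extraction:
#' candidate voxels are those whose primary-channel intensity is at least
#' `config@primaryThreshold` and whose centre lies inside at least one
#' compartment. A voxel inside several (overlapping) compartments is assigned
#' to the one with the smallest normalised radial distance d / r(t), ties
#' going to the lower node id, which makes the assignment a deterministic
#' partition. Above-threshold voxels inside no compartment stay unassigned.
#'
#' @param tree a [NeuronTree-class] in the same physical frame as the stack.
#' @param primary the primary-channel [ImageStack-class].
#' @param config an [ExtractionConfig-class].
#' @return data.frame with one row per assigned voxel: 0-based indices
#'   `i, j, k`, the linear array index `voxel`, the owning `node` id and the
#'   normalised distance `ndist`. The stack dimensions are attached as
#'   attribute `dims`. Zero rows (with a warning) when nothing is assignable.
#' @export
assignVoxels <- function(tree, primary, config = ExtractionConfig()) {
  validObject(primary)
  dims <- dim(primary@voxels)
  spacing <- primary@spacing
  comps <- compartments(tree)
  pass <- primary@voxels >= config@primaryThreshold
  bestNd <- array(Inf, dims)
  bestId <- array(NA_integer_, dims)
  for (ci in order(comps$id)) {
    comp <- comps[ci, ]
    bb <- .compBBox(comp, spacing, dims)
    if (is.null(bb)) next
    ii <- bb[1, 1]:bb[1, 2]
    jj <- bb[2, 1]:bb[2, 2]
    kk <- bb[3, 1]:bb[3, 2]
    idx <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
    sub <- idx + 1L
    cand <- pass[sub] & bestNd[sub] > 0 # skip voxels already matched exactly on-axis
    if (!any(cand)) next
    idx <- idx[cand, , drop = FALSE]
    sub <- sub[cand, , drop = FALSE]
    res <- .containsPoints(comp, voxelCenter(idx, spacing))
    better <- res$inside & res$ndist < bestNd[sub]
    if (any(better)) {
      sub <- sub[better, , drop = FALSE]
      bestNd[sub] <- res$ndist[better]
      bestId[sub] <- comp$id
    }
  }
  hit <- which(!is.na(bestId))
  if (length(hit) == 0L) {
    warning("no voxel could be assigned to any compartment")
    out <- data.frame(
      i = integer(), j = integer(), k = integer(),
      voxel = integer(), node = integer(), ndist = numeric()
    )
    attr(out, "dims") <- dims
    return(out)
  }
  ijk <- arrayInd(hit, dims) - 1L
  out <- data.frame(
    i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
    voxel = hit, node = bestId[hit], ndist = bestNd[hit]
  )
  out <- out[order(out$voxel), ]
  rownames(out) <- NULL
  attr(out, "dims") <- dims
  out
}

#' Per-compartment channel statistics
#'
#' Given the candidate voxels assigned to one compartment, computes the
#' (ratio, mean, sd) triple for a secondary channel: the fraction of
#' candidates whose secondary intensity passes the channel threshold
#' (intensity >= threshold), the mean intensity of those passing voxels and
#' their population (divide-by-n) standard deviation. An empty candidate set,
#' or one with no passing voxel, yields (0, 0, 0); a single passing voxel has
#' sd 0.
#'
#' @param candidates integer vector of linear voxel indices (the `voxel`
#'   column of [assignVoxels()] restricted to one node).
#' @param secondary the secondary-channel [ImageStack-class].
#' @param threshold intensity threshold for this channel.
#' @return Named numeric vector c(ratio, mean, sd).
#' @examples
#' st <- ImageStack(array(c(10, 20, 30, 0), c(4, 1, 1)))
#' computeChannelStats(1:3, st, 15) # ratio 2/3, mean 25, sd 5
#' @export
computeChannelStats <- function(candidates, secondary, threshold) {
  if (length(candidates) == 0L) {
    return(c(ratio = 0, mean = 0, sd = 0))
  }
  v <- secondary@voxels[candidates]
  passing <- v[v >= threshold]
  n <- length(passing)
  if (n == 0L) {
    return(c(ratio = 0, mean = 0, sd = 0))
  }
  m <- mean(passing)
  s <- sqrt(sum((passing - m)^2) / n)
  c(ratio = n / length(candidates), mean = m, sd = s)
}

#' Construct an EswcSet
#'
#' @param tree a [NeuronTree-class].
#' @param stats numeric matrix, one row per node, 3 columns per channel
#'   (ratio, mean, sd).
#' @param channels character vector of channel names.
#' @param thresholds per-channel thresholds recorded in headers.
#' @return An [EswcSet-class].
#' @export
EswcSet <- function(tree, stats, channels = NULL, thresholds = numeric()) {
  if (is.null(channels)) {
    channels <- if (ncol(stats)) paste0("ch", seq_len(ncol(stats) / 3)) else character()
  }
  colnames(stats) <- as.vector(t(outer(channels, c("ratio", "mean", "sd"), paste, sep = ".")))
  new("EswcSet",
    tree = tree, stats = stats, channels = as.character(channels),
    thresholds = as.numeric(thresholds)
  )
}

#' @describeIn EswcSet The underlying morphology.
#' @param x an EswcSet.
#' @export
eswcTree <- function(x) x@tree

#' @describeIn EswcSet The statistics matrix (3 columns per channel).
#' @export
eswcStats <- function(x) x@stats

#' @describeIn EswcSet Channel names.
#' @export
eswcChannels <- function(x) x@channels

setMethod("show", "EswcSet", function(object) {
  cat(sprintf(
    "EswcSet: %d nodes, %d channel(s)%s\n", nrow(object@stats),
    length(object@channels),
    if (length(object@channels)) {
      sprintf(" [%s]", paste(object@channels, collapse = ", "))
    } else {
      ""
    }
  ))
})

#' Extract multi-channel statistics over a reconstruction
#'
#' The full extraction pipeline: assigns primary-passing voxels to
#' compartments once ([assignVoxels()]), then computes the (ratio, mean, sd)
#' triple of every compartment for every secondary channel
#' ([computeChannelStats()]). Node order and all seven morphology fields are
#' preserved unchanged.
#'
#' @param tree a [NeuronTree-class].
#' @param primary primary-channel [ImageStack-class].
#' @param secondaries list of secondary-channel [ImageStack-class] objects;
#'   all stacks must share dims and spacing.
#' @param config an [ExtractionConfig-class]; secondary thresholds default to
#'   the primary threshold.
#' @param channels optional character vector naming the secondary channels.
#' @return An [EswcSet-class].
#' @export
extractMultichannel <- function(tree, primary, secondaries = list(),
                                config = ExtractionConfig(), channels = NULL) {
  if (is(secondaries, "ImageStack")) secondaries <- list(secondaries)
  for (s in secondaries) {
    if (!identical(dim(s@voxels), dim(primary@voxels)) ||
      !isTRUE(all.equal(s@spacing, primary@spacing))) {
      stop("all channel stacks must share dimensions and spacing")
    }
  }
  C <- length(secondaries)
  thr <- config@secondaryThresholds
  if (length(thr) == 0L) thr <- rep(config@primaryThreshold, C)
  if (length(thr) != C) stop("need one secondary threshold per channel")
  asg <- assignVoxels(tree, primary, config)
  nd <- tree@nodes
  byNode <- split(asg$voxel, factor(asg$node, levels = nd$id))
  stats <- matrix(0, nrow = nrow(nd), ncol = 3L * C)
  for (ch in seq_len(C)) {
    for (r in seq_len(nrow(nd))) {
      stats[r, (3L * ch - 2L):(3L * ch)] <-
        computeChannelStats(byNode[[r]], secondaries[[ch]], thr[ch])
    }
  }
  EswcSet(tree, stats, channels = channels, thresholds = thr)
}

## ---- ESWC text format -----------------------------------------------------

#' Write an EswcSet as ESWC text
#'
#' One line per node: the 7 SWC fields followed, per channel in order, by
#' ratio, mean and sd -- 7 + 3C values per line (13 for two channels). The
#' header records the channel count, names, thresholds and (optionally)
#' spacing as `# key = value` lines.
#'
#' @param x an [EswcSet-class].
#' @param path optional output file path.
#' @param spacing optional numeric length-3 voxel spacing recorded in the
#'   header.
#' @return Character vector of lines.
#' @export
writeESWC <- function(x, path = NULL, spacing = NULL) {
  nd <- x@tree@nodes
  hdr <- c(
    x@tree@header,
    sprintf("# channels = %d", length(x@channels)),
    if (length(x@channels)) {
      sprintf("# channel_names = %s", paste(x@channels, collapse = " "))
    },
    if (length(x@thresholds)) {
      sprintf("# thresholds = %s", paste(.fmtNum(x@thresholds), collapse = " "))
    },
    if (!is.null(spacing)) {
      sprintf("# spacing = %s", paste(.fmtNum(spacing), collapse = " "))
    }
  )
  body <- .formatNodeLines(nd)
  if (ncol(x@stats)) {
    statTok <- apply(x@stats, 1, function(row) paste(.fmtNum(row), collapse = " "))
    body <- paste(body, statTok)
  }
  lines <- c(hdr, body)
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

#' Read ESWC text
#'
#' Inverse of [writeESWC()]. The channel count is taken from the
#' `# channels` header when present, otherwise inferred from the column
#' count; every data line must carry 7 + 3C values.
#'
#' @param text character lines, a single string, or a path with
#'   `isPath = TRUE`.
#' @param isPath treat `text` as a file path.
#' @return An [EswcSet-class].
#' @export
readESWC <- function(text, isPath = FALSE) {
  if (isPath) text <- readLines(text, warn = FALSE)
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  isComment <- grepl("^\\s*#", text)
  isBlank <- grepl("^\\s*$", text)
  header <- sub("^\\s*", "", text[isComment])
  dataLines <- which(!isComment & !isBlank)
  toks <- lapply(dataLines, function(ln) {
    tok <- suppressWarnings(as.numeric(strsplit(trimws(text[ln]), "[ \t]+")[[1]]))
    if (anyNA(tok)) stop(sprintf("line %d: non-numeric field", ln))
    tok
  })
  ncols <- unique(lengths(toks))
  if (length(ncols) > 1L) {
    stop("inconsistent column counts across ESWC lines")
  }
  ncols <- if (length(ncols)) ncols else 7L
  declared <- .headerValue(header, "channels")
  C <- if (!is.na(declared)) as.integer(declared) else (ncols - 7L) %/% 3L
  if (ncols != 7L + 3L * C) {
    stop(sprintf("ESWC lines have %d values; expected %d for %d channel(s)", ncols, 7L + 3L * C, C))
  }
  m <- if (length(toks)) do.call(rbind, toks) else matrix(numeric(), 0, ncols)
  chn <- .headerTokens(header, "channel_names")
  if (length(chn) != C) chn <- if (C > 0) paste0("ch", seq_len(C)) else character()
  thr <- suppressWarnings(as.numeric(.headerTokens(header, "thresholds")))
  if (length(thr) != C) thr <- numeric()
  keep <- !grepl("^#\\s*(channels|channel_names|thresholds|spacing)\\s*=", header)
  tree <- NeuronTree(as.data.frame(m[, 1:7, drop = FALSE]), header = header[keep])
  EswcSet(tree, m[, -(1:7), drop = FALSE], channels = chn, thresholds = thr)
}

## First "# key = v1 v2 ..." header line -> token vector (character(0) if absent).
.headerTokens <- function(header, key) {
  pat <- sprintf("^#\\s*%s\\s*=\\s*", key)
  hit <- grep(pat, header, value = TRUE)
  if (length(hit) == 0L) {
    return(character())
  }
  strsplit(trimws(sub(pat, "", hit[1])), "[ \t]+")[[1]]
}

.headerValue <- function(header, key) {
  tok <- .headerTokens(header, key)
  if (length(tok)) tok[1] else NA_character_
}

## ---- back-compatible #CHANNELSWC dialect ----------------------------------

#' Write the back-compatible SWC with a #CHANNELSWC block
#'
#' Emits the original 7-field SWC body verbatim, then a `#CHANNELSWC` tag
#' line, then one comment line per node appending the fraction and mean of
#' every subcellular channel: `# <id> <ratio> <mean> [<ratio> <mean> ...]`.
#' Any standard SWC parser that skips '#' lines recovers the original
#' morphology exactly.
#'
#' @param x an [EswcSet-class].
#' @param path optional output file path.
#' @return Character vector of lines.
#' @export
writeChannelSWC <- function(x, path = NULL) {
  nd <- x@tree@nodes
  C <- length(x@channels)
  lines <- c(x@tree@header, .formatNodeLines(nd), "#CHANNELSWC")
  if (C > 0 && nrow(nd)) {
    rm <- x@stats[, as.vector(rbind(3 * seq_len(C) - 2, 3 * seq_len(C) - 1)), drop = FALSE]
    ann <- apply(rm, 1, function(row) paste(.fmtNum(row), collapse = " "))
    lines <- c(lines, paste("#", nd$id, ann))
  }
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

#' Read the #CHANNELSWC block back
#'
#' Recovers the morphology and the per-node (ratio, mean) pairs from a
#' back-compatible file written by [writeChannelSWC()]. Standard deviations
#' are not stored in this dialect and come back as NA.
#'
#' @param text character lines, a single string, or a path with
#'   `isPath = TRUE`.
#' @param isPath treat `text` as a file path.
#' @return list with `tree` (a [NeuronTree-class]) and `stats` (data.frame of
#'   id plus ratio/mean per channel; NULL when the block is empty).
#' @export
readChannelSWC <- function(text, isPath = FALSE) {
  if (isPath) text <- readLines(text, warn = FALSE)
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  tree <- parseSWC(text)
  tag <- grep("^\\s*#CHANNELSWC\\s*$", text)
  stats <- NULL
  if (length(tag)) {
    block <- text[-seq_len(tag[1])]
    block <- block[grepl("^\\s*#", block)]
    rows <- lapply(block, function(ln) {
      suppressWarnings(as.numeric(strsplit(trimws(sub("^\\s*#\\s*", "", ln)), "[ \t]+")[[1]]))
    })
    rows <- rows[vapply(rows, function(r) length(r) >= 3 && !anyNA(r), logical(1))]
    if (length(rows)) {
      m <- do.call(rbind, rows)
      C <- (ncol(m) - 1L) %/% 2L
      stats <- data.frame(id = as.integer(m[, 1]))
      for (ch in seq_len(C)) {
        stats[[sprintf("ch%d.ratio", ch)]] <- m[, 2 * ch]
        stats[[sprintf("ch%d.mean", ch)]] <- m[, 2 * ch + 1]
      }
    }
  }
  list(tree = tree, stats = stats)
}
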