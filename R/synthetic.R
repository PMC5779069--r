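## Synthetic fixtures: seeded random morphologies, rasterized membrane
## channels, painted secondary channels with recorded ground-truth statistics,
## and scripted dynamic event series with gold-standard SWCX output.

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG stream.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Rodrigues rotation of unit vector v by angle (radians) around unit axis k.
.rotate <- function(v, k, angle) {
  v * cos(angle) + c(
    k[2] * v[3] - k[3] * v[2],
    k[3] * v[1] - k[1] * v[3],
    k[1] * v[2] - k[2] * v[1]
  ) * sin(angle) + k * sum(k * v) * (1 - cos(angle))
}

## A unit vector perpendicular to u.
.perp <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e <- ref - sum(ref * u) * u
  e / sqrt(sum(e^2))
}

.round6 <- function(x) round(x, 6)

#' Generate a random branched morphology
#'
#' Grows a binary tree from a spherical soma: segments of a few nodes each,
#' whose lengths and inter-node directions are drawn per seed, split at
#' branch points with a symmetric branch angle until the requested number of
#' bifurcations is reached. Radii taper multiplicatively per segment. For a
#' binary tree the terminal count equals `nBranchPoints + 1`. All coordinates
#' and radii are rounded to 6 decimals so written files round-trip exactly.
#' The same seed always yields the identical morphology.
#'
#' @param nBranchPoints number of bifurcations (0 gives an unbranched chain).
#' @param segmentLength c(mean, sd) of segment length in um.
#' @param radiusTaper multiplicative radius factor per segment.
#' @param branchAngle c(mean, sd) of the full angle between sibling branches,
#'   degrees.
#' @param nodesPerSegment nodes per inter-branch segment.
#' @param somaRadius soma (root) radius in um.
#' @param trunkRadius initial neurite radius in um.
#' @param origin soma position (um).
#' @param seed RNG seed; determinism is byte-for-byte in the written file.
#' @return A [NeuronTree-class] with a type-1 soma root and type-3 dendrites.
#' @export
generateMorphology <- function(nBranchPoints = 4, segmentLength = c(8, 2),
                               radiusTaper = 0.85, nodesPerSegment = 3,
                               branchAngle = c(50, 10), somaRadius = 2,
                               trunkRadius = 1.2, origin = c(0, 0, 0),
                               seed = 1) {
  stopifnot(nBranchPoints >= 0, segmentLength[1] > 0, radiusTaper > 0)
  .withSeed(seed, {
    rows <- list()
    nextId <- 1L
    addNode <- function(type, pos, radius, parent) {
      rows[[length(rows) + 1L]] <<- data.frame(
        id = nextId, type = type, x = .round6(pos[1]), y = .round6(pos[2]),
        z = .round6(pos[3]), radius = .round6(max(radius, 0.05)), parent = parent
      )
      nextId <<- nextId + 1L
      nextId - 1L
    }
    rootId <- addNode(1L, origin, somaRadius, -1L)
    grow <- function(parentId, pos, dir, radius, splits) {
      len <- max(1, stats::rnorm(1, segmentLength[1], segmentLength[2]))
      step <- len / nodesPerSegment
      for (i in seq_len(nodesPerSegment)) {
        jit <- stats::rnorm(1, 0, 3) * pi / 180
        dir <- .rotate(dir, .perp(dir), jit)
        dir <- dir / sqrt(sum(dir^2))
        pos <- pos + dir * step
        parentId <- addNode(3L, pos, radius, parentId)
      }
      if (splits > 0L) {
        ang <- max(10, stats::rnorm(1, branchAngle[1], branchAngle[2])) * pi / 180
        axis <- .perp(dir)
        spin <- stats::runif(1, 0, 2 * pi)
        axis <- .rotate(axis, dir, spin)
        left <- if (splits > 1L) sample.int(splits, 1L) - 1L else 0L
        d1 <- .rotate(dir, axis, ang / 2)
        d2 <- .rotate(dir, axis, -ang / 2)
        grow(parentId, pos, d1, radius * radiusTaper, left)
        grow(parentId, pos, d2, radius * radiusTaper, splits - 1L - left)
      }
    }
    dir0 <- stats::rnorm(3)
    dir0 <- dir0 / sqrt(sum(dir0^2))
    grow(rootId, origin, dir0, trunkRadius, as.integer(nBranchPoints))
    NeuronTree(do.call(rbind, rows), header = "# synthetic morphology")
  })
}

## Logical mask of voxels whose centres lie inside any compartment.
.insideMask <- function(tree, dims, spacing) {
  comps <- compartments(tree)
  mask <- array(FALSE, dims)
  for (ci in seq_len(nrow(comps))) {
    comp <- comps[ci, ]
    bb <- .compBBox(comp, spacing, dims)
    if (is.null(bb)) next
    idx <- as.matrix(expand.grid(i = bb[1, 1]:bb[1, 2], j = bb[2, 1]:bb[2, 2], k = bb[3, 1]:bb[3, 2]))
    res <- .containsPoints(comp, voxelCenter(idx, spacing))
    if (any(res$inside)) {
      mask[idx[res$inside, , drop = FALSE] + 1L] <- TRUE
    }
  }
  mask
}

#' Rasterize a morphology into a membrane channel
#'
#' Reverse-generates an image stack from a reconstruction: every voxel whose
#' centre lies inside at least one compartment receives the stated intensity,
#' all others zero. Running the extraction on (tree, rasterized stack)
#' therefore assigns exactly the painted voxels.
#'
#' @param tree a [NeuronTree-class]; must fit inside the physical extent
#'   `dims * spacing` (including radii).
#' @param dims voxel counts (nx, ny, nz).
#' @param spacing um per voxel.
#' @param intensity painted intensity (default 255).
#' @param bitDepth 8 or 16.
#' @return An [ImageStack-class].
#' @export
rasterizeMembrane <- function(tree, dims, spacing = c(1, 1, 1), intensity = 255,
                              bitDepth = 8L) {
  nd <- tree@nodes
  if (nrow(nd)) {
    extent <- dims * spacing
    lo <- c(min(nd$x - nd$radius), min(nd$y - nd$radius), min(nd$z - nd$radius))
    hi <- c(max(nd$x + nd$radius), max(nd$y + nd$radius), max(nd$z + nd$radius))
    if (any(lo < 0) || any(hi > extent)) {
      stop("tree does not fit inside the stack extent")
    }
  }
  vox <- array(0, dims)
  if (nrow(nd)) vox[.insideMask(tree, dims, spacing)] <- intensity
  ImageStack(vox, spacing = spacing, bitDepth = as.integer(bitDepth))
}

#' Per-compartment signal specification
#'
#' Target (ratio, mean, sd) triples for painting a secondary channel. The two
#' preset modes emulate the interpretation regimes of compartment statistics:
#' `homogeneous` (ratio near 1, low sd -- diffuse substrate) and `punctate`
#' (ratio near 0, high sd -- strong localized puncta).
#'
#' @param nodeIds integer vector of node ids to specify.
#' @param mode "homogeneous", "punctate", or "custom".
#' @param ratio,mean,sd explicit per-node targets (recycled); required for
#'   `mode = "custom"`, override the preset otherwise. `mean` must be at or
#'   above the intended threshold.
#' @return data.frame(node, ratio, mean, sd).
#' @export
signalSpec <- function(nodeIds, mode = c("homogeneous", "punctate", "custom"),
                       ratio = NULL, mean = NULL, sd = NULL) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    homogeneous = list(ratio = 0.9, mean = 120, sd = 6),
    punctate = list(ratio = 0.15, mean = 160, sd = 45),
    custom = list(ratio = NULL, mean = NULL, sd = NULL)
  )
  ratio <- ratio %||% defaults$ratio
  mean <- mean %||% defaults$mean
  sd <- sd %||% defaults$sd
  if (is.null(ratio) || is.null(mean) || is.null(sd)) {
    stop("mode = 'custom' requires explicit ratio, mean and sd")
  }
  stopifnot(all(ratio >= 0 & ratio <= 1), all(sd >= 0))
  data.frame(
    node = as.integer(nodeIds),
    ratio = rep_len(ratio, length(nodeIds)),
    mean = rep_len(mean, length(nodeIds)),
    sd = rep_len(sd, length(nodeIds))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Paint a secondary channel with known per-compartment statistics
#'
#' For every compartment with n assigned candidate voxels, exactly
#' `round(ratio * n)` voxels (a seeded draw) receive intensities sampled from
#' a normal(mean, sd) truncated below at the threshold (rejection sampling)
#' and clamped to the intensity range; every other voxel of the stack gets
#' sub-threshold background noise, uniform integers in [0, threshold - 1], so
#' thresholding at `intensity >= threshold` is unambiguous. The realized
#' (ratio, mean, sd) of the painted integer values -- not the nominal spec --
#' are recorded and are the ground truth for recovery tests.
#'
#' @param assignment voxel assignment from [assignVoxels()].
#' @param spec data.frame(node, ratio, mean, sd) from [signalSpec()].
#' @param threshold intensity threshold the channel will be extracted with.
#' @param spacing um per voxel for the painted stack.
#' @param bitDepth 8 or 16.
#' @param seed RNG seed.
#' @return list with `stack` (the painted [ImageStack-class]) and `truth`
#'   (data.frame node, n, ratio, mean, sd of realized values).
#' @export
paintChannel <- function(assignment, spec, threshold = 15, spacing = c(1, 1, 1),
                         bitDepth = 8L, seed = 1) {
  dims <- attr(assignment, "dims")
  if (is.null(dims)) stop("assignment must carry a 'dims' attribute")
  vmax <- if (bitDepth == 16L) 65535 else 255
  if (any(spec$mean < threshold)) stop("spec mean must be >= threshold")
  .withSeed(seed, {
    vox <- array(
      sample.int(as.integer(threshold), prod(dims), replace = TRUE) - 1L,
      dims
    )
    truth <- list()
    for (r in seq_len(nrow(spec))) {
      cand <- assignment$voxel[assignment$node == spec$node[r]]
      n <- length(cand)
      k <- round(spec$ratio[r] * n)
      if (k > 0) {
        chosen <- cand[sample.int(n, k)]
        vals <- numeric(0)
        while (length(vals) < k) {
          draw <- stats::rnorm(k, spec$mean[r], spec$sd[r])
          vals <- c(vals, draw[draw >= threshold])
        }
        vals <- pmin(round(vals[seq_len(k)]), vmax)
        vox[chosen] <- vals
        m <- mean(vals)
        truth[[r]] <- data.frame(
          node = spec$node[r], n = n, ratio = k / n, mean = m,
          sd = sqrt(sum((vals - m)^2) / k)
        )
      } else {
        truth[[r]] <- data.frame(node = spec$node[r], n = n, ratio = 0, mean = 0, sd = 0)
      }
    }
    list(
      stack = ImageStack(vox, spacing = spacing, bitDepth = as.integer(bitDepth)),
      truth = do.call(rbind, truth)
    )
  })
}

## ---- scripted dynamics ----------------------------------------------------

## Children count per node id (named integer vector).
.childCounts <- function(nd) {
  cnt <- table(factor(nd$parent[nd$parent != -1L], levels = nd$id))
  stats::setNames(as.integer(cnt), nd$id)
}

## Terminal chain from terminal `tid` up to (exclusive) the nearest branch
## point or root; returns row indices in tree order.
.terminalChain <- function(nd, tid) {
  cnt <- .childCounts(nd)
  chain <- integer()
  cur <- tid
  repeat {
    chain <- c(chain, match(cur, nd$id))
    p <- nd$parent[match(cur, nd$id)]
    if (p == -1L) break
    if (cnt[[as.character(p)]] != 1L || nd$parent[match(p, nd$id)] == -1L) break
    cur <- p
  }
  sort(chain)
}

## Row indices of the subtree rooted at node id (inclusive).
.subtreeRows <- function(nd, id) {
  keep <- nd$id == id
  repeat {
    grow <- nd$parent %in% nd$id[keep] & !keep
    if (!any(grow)) break
    keep <- keep | grow
  }
  which(keep)
}

#' Simulate a scripted dynamic event series
#'
#' Applies a script of dynamic events -- terminal/interstitial branch
#' extension, local scaling (axial stretch or radius change), rotation/
#' deformation, terminal branch retraction and branch re-emergence -- to a
#' starting morphology, one transition per time step, preserving node ids of
#' untouched structure. Besides the per-time-point static trees it emits the
#' gold-standard SWCX table and per-transition event reports that the
#' annotation/consolidation pipeline must reproduce exactly.
#'
#' Script rows are (time, kind, target, magnitude) with `time` in 1..T-1:
#' \describe{
#'   \item{extend}{`target` an existing node id (a terminal gives terminal
#'     extension, an internal node interstitial branching); `magnitude` the
#'     branch length in um; new nodes are inserted after the target (terminal
#'     case) or after the target's entire subtree (interstitial case).}
#'   \item{scale}{`target` a non-root node; positive `magnitude` displaces it
#'     by that many um along its parent axis (stretch), negative scales its
#'     radius by `|magnitude|`.}
#'   \item{deform}{displaces the target perpendicular to its parent axis by
#'     `magnitude` um.}
#'   \item{retract}{`target` a terminal node; removes the terminal chain up
#'     to the nearest branch point.}
#'   \item{re-emerge}{`target` the terminal id of a previously retracted
#'     chain; restores it with identical ids and geometry.}
#' }
#'
#' When `script` is NULL a random feasible script with `nTimepoints` time
#' points is drawn under `seed` and returned in the output.
#'
#' @param tree starting [NeuronTree-class] (time 0).
#' @param script data.frame(time, kind, target, magnitude), or NULL.
#' @param nTimepoints number of time points when drawing a random script.
#' @param maxEventsPerStep at most this many random events per transition.
#' @param timestamps per-time-point timestamps for the gold table.
#' @param seed RNG seed for random scripts and branch directions.
#' @return list with `trees` (length-T list of [NeuronTree-class]), `gold`
#'   (the gold [SwcxTable-class]), `reports` (per-transition
#'   data.frame(id, code) of dynamic events) and `script`.
#' @export
simulateDynamics <- function(tree, script = NULL, nTimepoints = 4,
                             maxEventsPerStep = 2, timestamps = NULL,
                             seed = 1) {
  .withSeed(seed, {
    random <- is.null(script)
    T <- if (random || nrow(script) == 0L) nTimepoints else max(script$time) + 1L
    if (T < 2L) stop("need at least two time points")
    trees <- vector("list", T)
    trees[[1L]] <- tree
    registry <- list() # retracted chains by terminal id
    master <- tree@nodes$id
    nextId <- max(master) + 1L
    blocks <- vector("list", T - 1L) # per-transition (id, code, geometry)
    reports <- vector("list", T - 1L)
    scriptRows <- list()
    codes <- eventCodes()

    for (t in seq_len(T - 1L)) {
      nd <- trees[[t]]@nodes
      eventCode <- integer() # named by node id

      evs <- if (random) {
        .randomStepEvents(nd, registry, maxEventsPerStep)
      } else {
        script[script$time == t, , drop = FALSE]
      }
      if (nrow(evs)) {
        for (e in seq_len(nrow(evs))) {
          kind <- as.character(evs$kind[e])
          target <- as.integer(evs$target[e])
          mag <- as.numeric(evs$magnitude[e])
          scriptRows[[length(scriptRows) + 1L]] <- data.frame(
            time = t, kind = kind, target = target, magnitude = mag
          )
          if (kind == "extend") {
            row <- match(target, nd$id)
            if (is.na(row)) stop(sprintf("script targets nonexistent node %d", target))
            cnt <- .childCounts(nd)
            terminal <- cnt[[as.character(target)]] == 0L
            prow <- match(nd$parent[row], nd$id)
            dir <- if (terminal && !is.na(prow)) {
              c(nd$x[row] - nd$x[prow], nd$y[row] - nd$y[prow], nd$z[row] - nd$z[prow])
            } else {
              stats::rnorm(3)
            }
            if (sum(dir^2) == 0) dir <- stats::rnorm(3)
            dir <- dir / sqrt(sum(dir^2))
            if (!terminal) dir <- .perp(dir) # interstitial: branch sideways
            nNew <- 2L
            step <- mag / nNew
            newRows <- list()
            pos <- c(nd$x[row], nd$y[row], nd$z[row])
            pid <- target
            for (i in seq_len(nNew)) {
              pos <- pos + dir * step
              newRows[[i]] <- data.frame(
                id = nextId, type = 3L, x = .round6(pos[1]), y = .round6(pos[2]),
                z = .round6(pos[3]), radius = .round6(max(0.05, nd$radius[row] * 0.9)),
                parent = pid
              )
              pid <- nextId
              nextId <- nextId + 1L
            }
            newRows <- do.call(rbind, newRows)
            insAt <- if (terminal) row else max(.subtreeRows(nd, target))
            nd <- rbind(
              nd[seq_len(insAt), , drop = FALSE], newRows,
              if (insAt < nrow(nd)) nd[(insAt + 1L):nrow(nd), , drop = FALSE]
            )
            rownames(nd) <- NULL
            eventCode[as.character(newRows$id)] <- codes[["extension"]]
          } else if (kind == "scale") {
            row <- match(target, nd$id)
            prow <- match(nd$parent[row], nd$id)
            if (is.na(row) || is.na(prow)) stop("scale target must be a non-root node")
            if (mag >= 0) {
              ax <- c(nd$x[row] - nd$x[prow], nd$y[row] - nd$y[prow], nd$z[row] - nd$z[prow])
              ax <- ax / sqrt(sum(ax^2))
              nd$x[row] <- .round6(nd$x[row] + ax[1] * mag)
              nd$y[row] <- .round6(nd$y[row] + ax[2] * mag)
              nd$z[row] <- .round6(nd$z[row] + ax[3] * mag)
            } else {
              nd$radius[row] <- .round6(nd$radius[row] * abs(mag))
            }
            eventCode[as.character(target)] <- codes[["local_scaling"]]
          } else if (kind == "deform") {
            row <- match(target, nd$id)
            prow <- match(nd$parent[row], nd$id)
            if (is.na(row) || is.na(prow)) stop("deform target must be a non-root node")
            ax <- c(nd$x[row] - nd$x[prow], nd$y[row] - nd$y[prow], nd$z[row] - nd$z[prow])
            ax <- ax / sqrt(sum(ax^2))
            pp <- .perp(ax)
            nd$x[row] <- .round6(nd$x[row] + pp[1] * mag)
            nd$y[row] <- .round6(nd$y[row] + pp[2] * mag)
            nd$z[row] <- .round6(nd$z[row] + pp[3] * mag)
            eventCode[as.character(target)] <- codes[["rotation_deformation"]]
          } else if (kind == "retract") {
            rowsIdx <- .terminalChain(nd, target)
            if (.childCounts(nd)[[as.character(target)]] != 0L) {
              stop(sprintf("retract target %d is not a terminal", target))
            }
            chainIds <- nd$id[rowsIdx]
            top <- rowsIdx[!(nd$parent[rowsIdx] %in% chainIds)]
            registry[[as.character(target)]] <- list(
              rows = nd[rowsIdx, , drop = FALSE],
              anchor = nd$parent[top[1L]]
            )
            eventCode[as.character(nd$id[rowsIdx])] <- codes[["retraction"]]
            nd <- nd[-rowsIdx, , drop = FALSE]
            rownames(nd) <- NULL
          } else if (kind == "re-emerge") {
            entry <- registry[[as.character(target)]]
            if (is.null(entry)) stop(sprintf("no retracted branch with terminal %d", target))
            if (!(entry$anchor %in% nd$id)) {
              stop("re-emergence anchor no longer present")
            }
            ## restore the chain at its original position in the global node
            ## order (node ordering is stable across time points)
            firstPos <- match(entry$rows$id[1L], master)
            before <- which(match(nd$id, master) < firstPos)
            insAt <- if (length(before)) max(before) else match(entry$anchor, nd$id)
            nd <- rbind(
              nd[seq_len(insAt), , drop = FALSE], entry$rows,
              if (insAt < nrow(nd)) nd[(insAt + 1L):nrow(nd), , drop = FALSE]
            )
            rownames(nd) <- NULL
            eventCode[as.character(entry$rows$id)] <- codes[["re_emergence"]]
            registry[[as.character(target)]] <- NULL
          } else {
            stop(sprintf("unknown event kind '%s'", kind))
          }
        }
      }
      trees[[t + 1L]] <- NeuronTree(nd, header = trees[[t]]@header)
      ## the union row order follows the node order of the per-time-point
      ## files: new nodes slot in after their surviving predecessor
      master <- .mergeOrder(master, nd$id)
      ## gold block: every present node links to itself unless tagged
      link <- ifelse(
        as.character(nd$id) %in% names(eventCode),
        eventCode[as.character(nd$id)], nd$id
      )
      blocks[[t]] <- data.frame(
        id = nd$id, link = as.integer(link), type = nd$type,
        x = nd$x, y = nd$y, z = nd$z, radius = nd$radius, parent = nd$parent
      )
      rep <- data.frame(
        id = as.integer(names(eventCode)), code = as.integer(eventCode)
      )
      reports[[t]] <- rep[order(match(rep$id, master)), , drop = FALSE]
      rownames(reports[[t]]) <- NULL
    }

    if (is.null(timestamps)) timestamps <- seq_len(T) - 1
    gold <- .goldSwcx(master, trees[[1L]], blocks, timestamps)
    list(
      trees = trees, gold = gold, reports = reports,
      script = if (length(scriptRows)) {
        do.call(rbind, scriptRows)
      } else {
        data.frame(
          time = integer(), kind = character(), target = integer(),
          magnitude = numeric()
        )
      }
    )
  })
}

## Random feasible events for one transition. The `used` set keeps events of
## one step independent: a node is targeted at most once, and a moved node's
## parent and children are frozen so the parent-axis the classifier sees (the
## previous time point's) is also the axis the displacement was built along.
.randomStepEvents <- function(nd, registry, maxEvents) {
  cnt <- .childCounts(nd)
  terminals <- nd$id[cnt[as.character(nd$id)] == 0L & nd$parent != -1L]
  internals <- nd$id[cnt[as.character(nd$id)] == 1L & nd$parent != -1L]
  nEv <- sample.int(maxEvents + 1L, 1L) - 1L
  out <- list()
  used <- integer()
  pick1 <- function(pool) pool[sample.int(length(pool), 1L)]
  relatives <- function(id) {
    c(id, nd$parent[match(id, nd$id)], nd$id[nd$parent == id])
  }
  for (i in seq_len(nEv)) {
    kinds <- c("extend", "scale", "deform")
    if (length(setdiff(terminals, used)) > 1L) kinds <- c(kinds, "retract")
    if (length(registry)) kinds <- c(kinds, "re-emerge")
    kind <- pick1(kinds)
    if (kind == "extend") {
      pool <- setdiff(c(terminals, internals), used)
      if (!length(pool)) next
      tgt <- pick1(pool)
      out[[length(out) + 1L]] <- data.frame(
        time = NA, kind = "extend", target = tgt,
        magnitude = round(stats::runif(1, 2, 6), 3)
      )
      used <- c(used, tgt)
    } else if (kind == "scale") {
      radiusOnly <- stats::runif(1) < 0.5
      pool <- setdiff(nd$id[nd$parent != -1L], used)
      ## radius factors stay away from 1 and targets keep radii large enough
      ## that the change clears the radius tolerance
      if (radiusOnly) pool <- intersect(pool, nd$id[nd$radius >= 0.05])
      if (!length(pool)) next
      tgt <- pick1(pool)
      mag <- if (radiusOnly) {
        -round(pick1(c(stats::runif(1, 0.4, 0.7), stats::runif(1, 1.4, 2))), 3)
      } else {
        round(stats::runif(1, 0.5, 2), 3)
      }
      out[[length(out) + 1L]] <- data.frame(
        time = NA, kind = "scale", target = tgt, magnitude = mag
      )
      used <- c(used, if (radiusOnly) tgt else relatives(tgt))
    } else if (kind == "deform") {
      pool <- setdiff(nd$id[nd$parent != -1L], used)
      if (!length(pool)) next
      tgt <- pick1(pool)
      out[[length(out) + 1L]] <- data.frame(
        time = NA, kind = "deform", target = tgt,
        magnitude = round(stats::runif(1, 0.5, 2), 3)
      )
      used <- c(used, relatives(tgt))
    } else if (kind == "retract") {
      pool <- setdiff(terminals, used)
      if (!length(pool)) next
      tgt <- pick1(pool)
      chain <- .terminalChain(nd, tgt)
      out[[length(out) + 1L]] <- data.frame(
        time = NA, kind = "retract", target = tgt, magnitude = 0
      )
      used <- c(used, nd$id[chain], nd$parent[chain])
      terminals <- setdiff(terminals, nd$id[chain])
    } else { # re-emerge
      pool <- setdiff(as.integer(names(registry)), used)
      pool <- pool[vapply(pool, function(p) {
        a <- registry[[as.character(p)]]$anchor
        a %in% nd$id && !(a %in% used)
      }, logical(1))]
      if (!length(pool)) next
      tgt <- pick1(pool)
      out[[length(out) + 1L]] <- data.frame(
        time = NA, kind = "re-emerge", target = tgt, magnitude = 0
      )
      used <- c(used, tgt, registry[[as.character(tgt)]]$rows$id)
      registry[[as.character(tgt)]] <- NULL
    }
  }
  if (length(out)) {
    do.call(rbind, out)
  } else {
    data.frame(
      time = integer(), kind = character(), target = integer(),
      magnitude = numeric()
    )
  }
}

## Assemble the gold SWCX matrix from the simulator's own bookkeeping.
.goldSwcx <- function(master, tree0, blocks, timestamps) {
  T <- length(blocks) + 1L
  n <- length(master)
  m <- matrix(0, nrow = n, ncol = 7L * T)
  m[, 1] <- master
  hit <- match(master, tree0@nodes$id)
  pres <- !is.na(hit)
  m[pres, 2:7] <- as.matrix(
    tree0@nodes[hit[pres], c("type", "x", "y", "z", "radius", "parent")]
  )
  for (t in seq_along(blocks)) {
    b <- blocks[[t]]
    hit <- match(master, b$id)
    pres <- !is.na(hit)
    m[pres, 7L * t + 1:7] <- as.matrix(
      b[hit[pres], c("link", "type", "x", "y", "z", "radius", "parent")]
    )
  }
  new("SwcxTable",
    table = m, timestamps = as.numeric(timestamps), channels = character(),
    header = character()
  )
}
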