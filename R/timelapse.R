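## Time-varying reconstructions: event classification between consecutive
## morphologies, temporal-parent linking, consolidation into the SWCX table,
## per-timepoint extraction, and the combined multi-signal layout.

#' Default tolerances for temporal classification
#'
#' @param pos positional tolerance in um below which a node counts as
#'   unmoved.
#' @param rad radius tolerance in um below which the radius counts as
#'   unchanged.
#' @param angleDeg angular tolerance in degrees: a displacement within this
#'   angle of the parent-axis direction is local scaling rather than
#'   rotation/deformation.
#' @param match matching radius in um for nearest-neighbour correspondence.
#' @return Named list of tolerances.
#' @export
timelapseTolerances <- function(pos = 0.01, rad = 0.01, angleDeg = 15, match = 1.0) {
  list(pos = pos, rad = rad, angleDeg = angleDeg, match = match)
}

#' Classify the dynamic event of one node between two time points
#'
#' The decision cascade for a single node across one transition:
#' absent-to-present is an extension (-1), or a re-emergence (-5) when the
#' node existed at some earlier time (extension following a retraction at the
#' same location); present-to-absent is a terminal retraction (-4, recorded
#' in the transition report while the node's block is written absent);
#' present-to-present with position and radius within tolerance links to the
#' temporal parent (the positive id of the corresponding node at the previous
#' time point); a displacement within `angleDeg` of the parent-axis
#' direction, or a pure radius change, is local scaling (-2); anything else
#' is rotation/deformation (-3).
#'
#' @param curr named list/row with x, y, z, radius for the node at the later
#'   time, or NULL when absent.
#' @param prev the same at the earlier time (plus `id`), or NULL when absent.
#' @param everPresent was this node present at any time before `prev`?
#' @param prevParent position row of prev's parent (for the axis direction),
#'   or NULL for roots.
#' @param tol tolerances from [timelapseTolerances()].
#' @return Integer: a positive temporal-parent id or an event code from
#'   [eventCodes()].
#' @export
classifyEvent <- function(curr, prev, everPresent = FALSE, prevParent = NULL,
                          tol = timelapseTolerances()) {
  if (is.null(curr) && is.null(prev)) {
    stop("classifyEvent: node absent at both time points")
  }
  codes <- eventCodes()
  if (is.null(prev)) {
    return(if (everPresent) codes[["re_emergence"]] else codes[["extension"]])
  }
  if (is.null(curr)) {
    return(codes[["retraction"]])
  }
  dvec <- c(curr$x - prev$x, curr$y - prev$y, curr$z - prev$z)
  dpos <- sqrt(sum(dvec^2))
  drad <- abs(curr$radius - prev$radius)
  if (dpos <= tol$pos && drad <= tol$rad) {
    return(as.integer(prev$id))
  }
  if (dpos <= tol$pos) {
    return(codes[["local_scaling"]]) # radius-only change
  }
  if (!is.null(prevParent)) {
    axis <- c(prev$x - prevParent$x, prev$y - prevParent$y, prev$z - prevParent$z)
    alen <- sqrt(sum(axis^2))
    if (alen > 0) {
      cosang <- abs(sum(dvec * axis)) / (dpos * alen)
      cosang <- min(1, cosang)
      if (acos(cosang) * 180 / pi <= tol$angleDeg) {
        return(codes[["local_scaling"]])
      }
    }
  }
  codes[["rotation_deformation"]]
}

## Greedy nearest-neighbour correspondence within tol$match, constrained to
## preserve the parent-child relation where both ends are matched.
.nearestCorrespondence <- function(prev, curr, tol) {
  pn <- prev@nodes
  cn <- curr@nodes
  claimed <- rep(FALSE, nrow(pn))
  map <- integer(nrow(cn)) # prev id or NA
  map[] <- NA_integer_
  for (r in seq_len(nrow(cn))) {
    d <- sqrt((pn$x - cn$x[r])^2 + (pn$y - cn$y[r])^2 + (pn$z - cn$z[r])^2)
    d[claimed] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol$match) {
      ## parent consistency: if curr's parent is already matched, the
      ## candidate's parent must be that match (roots exempt)
      cp <- cn$parent[r]
      ok <- TRUE
      if (cp != -1L) {
        cpRow <- match(cp, cn$id)
        if (!is.na(cpRow) && cpRow < r && !is.na(map[cpRow])) {
          ok <- identical(as.integer(pn$parent[j]), map[cpRow]) || pn$parent[j] == -1L
        }
      }
      if (ok) {
        map[r] <- pn$id[j]
        claimed[j] <- TRUE
      }
    }
  }
  data.frame(curr = cn$id, prev = map)
}

#' Annotate the structural transition between two reconstructions
#'
#' Maps the later reconstruction node-by-node onto the earlier one and gives
#' every node of either time point exactly one classification: a positive
#' temporal-parent link for stable nodes or a dynamic event code
#' ([eventCodes()]). The default correspondence is id-based (the same node
#' keeps its id across files, as id-preserving editing workflows and the
#' synthetic simulator produce); `correspondence = "nearest"` instead matches
#' greedily by position within the matching radius, preserving parent-child
#' order. An explicit `map` (data.frame with columns `curr`, `prev`)
#' overrides both; two later nodes claiming the same earlier node is an
#' error.
#'
#' @param prev,curr [NeuronTree-class] objects at consecutive time points.
#' @param map optional explicit correspondence data.frame(curr, prev).
#' @param history integer vector of node ids present at any time before
#'   `prev` (drives the extension vs re-emergence distinction).
#' @param correspondence "ids" or "nearest".
#' @param tol tolerances from [timelapseTolerances()].
#' @return A [SwcTransition-class].
#' @export
annotateTransition <- function(prev, curr, map = NULL, history = integer(),
                               correspondence = c("ids", "nearest"),
                               tol = timelapseTolerances()) {
  correspondence <- match.arg(correspondence)
  pn <- prev@nodes
  cn <- curr@nodes
  if (is.null(map)) {
    map <- if (correspondence == "ids") {
      data.frame(curr = cn$id, prev = ifelse(cn$id %in% pn$id, cn$id, NA_integer_))
    } else {
      .nearestCorrespondence(prev, curr, tol)
    }
  }
  dup <- map$prev[!is.na(map$prev)][duplicated(map$prev[!is.na(map$prev)])]
  if (length(dup)) {
    stop(sprintf(
      "ambiguous correspondence: previous node(s) %s claimed more than once",
      paste(unique(dup), collapse = ", ")
    ))
  }
  pidx <- match(pn$parent, pn$id)
  rows <- vector("list", nrow(cn))
  for (r in seq_len(nrow(cn))) {
    prevId <- map$prev[match(cn$id[r], map$curr)]
    prevRow <- if (!is.na(prevId)) pn[match(prevId, pn$id), ] else NULL
    prevParent <- NULL
    if (!is.null(prevRow) && prevRow$parent != -1L) {
      prevParent <- pn[pidx[match(prevId, pn$id)], ]
    }
    code <- classifyEvent(
      curr = cn[r, ], prev = prevRow,
      everPresent = cn$id[r] %in% history, prevParent = prevParent, tol = tol
    )
    rows[[r]] <- data.frame(
      id = cn$id[r], code = as.integer(code), type = cn$type[r],
      x = cn$x[r], y = cn$y[r], z = cn$z[r], radius = cn$radius[r],
      parent = cn$parent[r]
    )
  }
  gone <- pn$id[!(pn$id %in% map$prev[!is.na(map$prev)])]
  for (g in gone) {
    rows[[length(rows) + 1L]] <- data.frame(
      id = g, code = eventCodes()[["retraction"]], type = 0L,
      x = 0, y = 0, z = 0, radius = 0, parent = 0L
    )
  }
  events <- do.call(rbind, rows)
  rownames(events) <- NULL
  new("SwcTransition", prev = prev, curr = curr, events = events)
}

#' @describeIn annotateTransition Rows of the annotation that are dynamic
#'   events (negative codes only; stable temporal-parent links are omitted).
#' @param x a [SwcTransition-class].
#' @export
transitionEvents <- function(x) {
  ev <- x@events[x@events$code < 0L, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

setMethod("show", "SwcTransition", function(object) {
  ev <- transitionEvents(object)
  cat(sprintf(
    "SwcTransition: %d -> %d nodes, %d dynamic event(s)\n",
    nrow(object@prev@nodes), nrow(object@curr@nodes), nrow(ev)
  ))
})

#' Annotate a whole series of reconstructions
#'
#' Threads [annotateTransition()] over consecutive pairs, maintaining the
#' presence history needed to tell re-emergences from first-time extensions.
#'
#' @param trees list of [NeuronTree-class] objects, one per time point, in
#'   temporal order.
#' @inheritParams annotateTransition
#' @return List of [SwcTransition-class], length `length(trees) - 1`.
#' @export
annotateSeries <- function(trees, correspondence = c("ids", "nearest"),
                           tol = timelapseTolerances()) {
  correspondence <- match.arg(correspondence)
  if (length(trees) < 2L) stop("need at least two time points")
  history <- integer()
  out <- vector("list", length(trees) - 1L)
  for (t in seq_len(length(trees) - 1L)) {
    out[[t]] <- annotateTransition(
      trees[[t]], trees[[t + 1L]],
      history = history, correspondence = correspondence, tol = tol
    )
    history <- union(history, trees[[t]]@nodes$id)
  }
  out
}

## Merge the node order of `ids` into the running master order: known ids
## advance the cursor, new ids are inserted right after it (this realises the
## ordering rule: new branches follow their parent, interstitial branches
## follow the displaced subtree, because that is where the per-time-point
## trees place them).
.mergeOrder <- function(master, ids) {
  pos <- 0L
  for (id in ids) {
    j <- match(id, master)
    if (!is.na(j)) {
      pos <- j
    } else {
      master <- append(master, id, after = pos)
      pos <- pos + 1L
    }
  }
  master
}

#' Consolidate annotated transitions into an SWCX table
#'
#' Builds the single union-of-nodes table from a chained series of
#' [SwcTransition-class] annotations: one row per node ever present, the
#' time-0 SWC fields first (zero-filled except for the id when the node does
#' not yet exist at time 0), then one 7-column block per later time point
#' carrying the link/event code and the updated geometry. Retracted and
#' absent nodes get all-zero blocks; the transition reports remain the
#' authoritative record of retraction events.
#'
#' @param transitions list of [SwcTransition-class]; `curr` of each must be
#'   `prev` of the next.
#' @param timestamps numeric vector, one per time point (defaults to
#'   0, 1, ..., T-1); units are free (minutes or days) and recorded verbatim.
#' @param header extra comment lines for the file header (e.g. global
#'   skeleton-scaling annotations as `# key = value`).
#' @return A [SwcxTable-class].
#' @export
consolidateSWCX <- function(transitions, timestamps = NULL, header = character()) {
  if (length(transitions) < 1L) stop("need at least one transition (two time points)")
  for (t in seq_along(transitions)[-1]) {
    if (!identical(transitions[[t - 1L]]@curr@nodes, transitions[[t]]@prev@nodes)) {
      stop(sprintf("chain inconsistency between transitions %d and %d", t - 1L, t))
    }
  }
  T <- length(transitions) + 1L
  if (is.null(timestamps)) timestamps <- seq_len(T) - 1
  if (length(timestamps) != T) stop("need one timestamp per time point")
  tree0 <- transitions[[1L]]@prev
  master <- tree0@nodes$id
  for (tr in transitions) master <- .mergeOrder(master, tr@curr@nodes$id)
  n <- length(master)
  m <- matrix(0, nrow = n, ncol = 7L * T)
  ## time-0 block
  m[, 1] <- master
  hit <- match(master, tree0@nodes$id)
  pres <- !is.na(hit)
  m[pres, 2:7] <- as.matrix(tree0@nodes[hit[pres], c("type", "x", "y", "z", "radius", "parent")])
  ## later blocks: link + updated geometry from the annotation
  for (t in seq_along(transitions)) {
    ev <- transitions[[t]]@events
    live <- ev[ev$code != eventCodes()[["retraction"]], , drop = FALSE]
    hit <- match(master, live$id)
    pres <- !is.na(hit)
    off <- 7L * t
    m[pres, off + 1:7] <- as.matrix(
      live[hit[pres], c("code", "type", "x", "y", "z", "radius", "parent")]
    )
  }
  new("SwcxTable",
    table = m, timestamps = as.numeric(timestamps),
    channels = character(), header = as.character(header)
  )
}

#' @describeIn SwcxTable Number of time points.
#' @param x a SwcxTable.
#' @export
swcxTimepoints <- function(x) length(x@timestamps)

#' @describeIn SwcxTable The raw consolidated matrix.
#' @export
swcxMatrix <- function(x) x@table

setMethod("show", "SwcxTable", function(object) {
  cat(sprintf(
    "SwcxTable: %d nodes x %d time points%s (%d columns)\n",
    nrow(object@table), length(object@timestamps),
    if (length(object@channels)) {
      sprintf(", %d channel(s)", length(object@channels))
    } else {
      ""
    },
    ncol(object@table)
  ))
})

## Column offset of time block t (0-based t) and block width for a table.
.blockGeom <- function(x) {
  C <- length(x@channels)
  list(width = 7L + 3L * C, C = C)
}

#' Extract the static morphology at one time point
#'
#' Drops rows absent at time `t` and returns the classic SWC tree whose
#' geometry is taken from that time point's block (time 0: the leading SWC
#' fields; later times: the 6 updated fields following the link column).
#'
#' @param x a [SwcxTable-class].
#' @param t 0-based time index (0 is the initial reconstruction).
#' @return A [NeuronTree-class].
#' @export
extractTimepoint <- function(x, t) {
  T <- length(x@timestamps)
  if (t < 0 || t >= T) stop(sprintf("time index %s out of range [0, %d]", t, T - 1L))
  g <- .blockGeom(x)
  off <- g$width * t
  m <- x@table
  if (t == 0) {
    present <- m[, 6] > 0 # a real node has positive radius; D15 rows are zero
    nd <- data.frame(
      id = m[present, 1], type = m[present, 2], x = m[present, 3],
      y = m[present, 4], z = m[present, 5], radius = m[present, 6],
      parent = m[present, 7]
    )
  } else {
    present <- m[, off + 1] != 0
    nd <- data.frame(
      id = m[present, 1], type = m[present, off + 2], x = m[present, off + 3],
      y = m[present, off + 4], z = m[present, off + 5],
      radius = m[present, off + 6], parent = m[present, off + 7]
    )
  }
  NeuronTree(nd)
}

#' Write an SwcxTable as SWCX text
#'
#' Header lines record the number of time points, the timestamps and any
#' channel metadata; every data row carries (7 + 3C) x T values.
#'
#' @param x a [SwcxTable-class].
#' @param path optional output file path.
#' @return Character vector of lines.
#' @export
writeSWCX <- function(x, path = NULL) {
  hdr <- c(
    x@header,
    sprintf("# timepoints = %d", length(x@timestamps)),
    sprintf("# timestamps = %s", paste(.fmtNum(x@timestamps), collapse = " ")),
    if (length(x@channels)) sprintf("# channels = %d", length(x@channels)),
    if (length(x@channels)) {
      sprintf("# channel_names = %s", paste(x@channels, collapse = " "))
    }
  )
  body <- apply(x@table, 1, function(row) paste(.fmtNum(row), collapse = " "))
  lines <- c(hdr, if (nrow(x@table)) body)
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

#' Read SWCX text
#'
#' Inverse of [writeSWCX()]. Rows must all have the same number of values,
#' consistent with the header-declared time point and channel counts.
#'
#' @param text character lines, a single string, or a path with
#'   `isPath = TRUE`.
#' @param isPath treat `text` as a file path.
#' @return A [SwcxTable-class].
#' @export
readSWCX <- function(text, isPath = FALSE) {
  if (isPath) text <- readLines(text, warn = FALSE)
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  isComment <- grepl("^\\s*#", text)
  isBlank <- grepl("^\\s*$", text)
  header <- sub("^\\s*", "", text[isComment])
  rows <- lapply(which(!isComment & !isBlank), function(ln) {
    tok <- suppressWarnings(as.numeric(strsplit(trimws(text[ln]), "[ \t]+")[[1]]))
    if (anyNA(tok)) stop(sprintf("line %d: non-numeric field", ln))
    tok
  })
  ncols <- unique(lengths(rows))
  if (length(ncols) > 1L) stop("ragged SWCX rows: inconsistent column counts")
  tsTok <- .headerTokens(header, "timestamps")
  ts <- suppressWarnings(as.numeric(tsTok))
  declaredT <- suppressWarnings(as.integer(.headerValue(header, "timepoints")))
  C <- suppressWarnings(as.integer(.headerValue(header, "channels")))
  if (is.na(C)) C <- 0L
  chn <- .headerTokens(header, "channel_names")
  if (length(chn) != C) chn <- if (C > 0) paste0("ch", seq_len(C)) else character()
  T <- if (!is.na(declaredT)) declaredT else length(ts)
  if (length(ts) != T) ts <- seq_len(T) - 1
  width <- 7L + 3L * C
  if (length(ncols) == 1L && ncols != width * T) {
    stop(sprintf(
      "SWCX rows have %d values; expected %d for %d time points and %d channel(s)",
      ncols, width * T, T, C
    ))
  }
  m <- if (length(rows)) do.call(rbind, rows) else matrix(numeric(), 0, width * T)
  keep <- !grepl("^#\\s*(timepoints|timestamps|channels|channel_names)\\s*=", header)
  new("SwcxTable",
    table = m, timestamps = ts, channels = chn, header = header[keep]
  )
}

#' Combine a time-varying table with per-time-point channel statistics
#'
#' Extends every time block (including time 0) of a pure SWCX table with
#' 3 statistics columns per imaging channel, taken from the per-time-point
#' multi-channel extractions. Nodes absent at a time point get zero
#' statistics. The node set of each [EswcSet-class] must match the static
#' morphology at that time point.
#'
#' @param x a [SwcxTable-class] with no channels yet.
#' @param records list of [EswcSet-class], one per time point.
#' @return A combined [SwcxTable-class] with (7 + 3C) x T columns.
#' @export
combineWithChannels <- function(x, records) {
  T <- length(x@timestamps)
  if (length(x@channels)) stop("table already carries channel statistics")
  if (length(records) != T) stop("need one EswcSet per time point")
  C <- length(records[[1L]]@channels)
  for (r in records) {
    if (length(r@channels) != C) stop("all time points must share the channel count")
  }
  n <- nrow(x@table)
  width <- 7L + 3L * C
  m <- matrix(0, nrow = n, ncol = width * T)
  for (t in seq_len(T) - 1L) {
    tp <- extractTimepoint(x, t)
    rec <- records[[t + 1L]]
    if (!setequal(tp@nodes$id, rec@tree@nodes$id)) {
      stop(sprintf("node-set mismatch between table and records at time %d", t))
    }
    m[, width * t + 1:7] <- x@table[, 7L * t + 1:7]
    hit <- match(x@table[, 1], rec@tree@nodes$id)
    pres <- !is.na(hit) & (if (t == 0) x@table[, 6] > 0 else x@table[, 7L * t + 1] != 0)
    m[pres, width * t + 7L + seq_len(3L * C)] <- rec@stats[hit[pres], , drop = FALSE]
  }
  new("SwcxTable",
    table = m, timestamps = x@timestamps,
    channels = records[[1L]]@channels, header = x@header
  )
}

## ---- per-transition annotated SWC interchange files -----------------------

#' Write one annotated transition as an SWC-like interchange file
#'
#' The intermediate per-transition dialect: one 7-column line per node of the
#' transition, with the neurite-type column temporarily repurposed to carry
#' the link/event code (stable nodes: the temporal parent id; dynamic nodes:
#' the negative event code; retracted nodes: -4 with zeroed geometry). This
#' keeps the file loadable by standard SWC tooling while the series is being
#' edited; the true neurite types are restored at consolidation time from the
#' previous time point (new branches default to dendrite, type 3).
#'
#' @param x a [SwcTransition-class].
#' @param path optional output file path.
#' @return Character vector of lines.
#' @export
writeAnnotatedSWC <- function(x, path = NULL) {
  ev <- x@events
  lines <- c(
    "# annotated transition (type column carries link/event code)",
    paste(
      ev$id, ev$code, .fmtNum(ev$x), .fmtNum(ev$y), .fmtNum(ev$z),
      .fmtNum(ev$radius), ev$parent
    )
  )
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

#' Read an annotated transition interchange file
#'
#' Inverse of [writeAnnotatedSWC()], given the reconstruction at the earlier
#' time point. Neurite types of stable/scaled/deformed nodes are recovered
#' from `prev`; newly extended nodes take `defaultType`.
#'
#' @param text character lines, a single string, or a path with
#'   `isPath = TRUE`.
#' @param prev the [NeuronTree-class] at the earlier time point.
#' @param defaultType structure type assigned to new (-1/-5) nodes whose type
#'   the dialect cannot carry.
#' @param isPath treat `text` as a file path.
#' @return A [SwcTransition-class].
#' @export
readAnnotatedSWC <- function(text, prev, defaultType = 3L, isPath = FALSE) {
  if (isPath) text <- readLines(text, warn = FALSE)
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  keep <- !grepl("^\\s*#", text) & !grepl("^\\s*$", text)
  rows <- lapply(which(keep), function(ln) {
    tok <- suppressWarnings(as.numeric(strsplit(trimws(text[ln]), "[ \t]+")[[1]]))
    if (length(tok) != 7L || anyNA(tok)) {
      stop(sprintf("line %d: expected 7 numeric fields", ln))
    }
    tok
  })
  m <- do.call(rbind, rows)
  pn <- prev@nodes
  codes <- as.integer(m[, 2])
  types <- integer(nrow(m))
  for (r in seq_len(nrow(m))) {
    id <- as.integer(m[r, 1])
    types[r] <- if (codes[r] == eventCodes()[["retraction"]]) {
      0L
    } else if (id %in% pn$id) {
      pn$type[match(id, pn$id)]
    } else {
      as.integer(defaultType)
    }
  }
  events <- data.frame(
    id = as.integer(m[, 1]), code = codes, type = types,
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    parent = as.integer(m[, 7])
  )
  live <- events[events$code != eventCodes()[["retraction"]], , drop = FALSE]
  curr <- NeuronTree(live[, c("id", "type", "x", "y", "z", "radius", "parent")])
  new("SwcTransition", prev = prev, curr = curr, events = events)
}
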