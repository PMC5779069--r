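## Classic SWC morphology: parsing, writing, navigation, the frustum
## compartment abstraction and structural diagnostics.

#' Event and marker codes used by time-varying reconstructions
#'
#' The five dynamic-event categories, plus the absent-node marker, as a named
#' integer vector. Positive values in a link field are not events but temporal
#' parents: the id of the corresponding node at the previous time point.
#'
#' @return Named integer vector: `extension` (-1, new terminal or interstitial
#'   branch), `local_scaling` (-2, stretch/contraction along the branch or
#'   radius change), `rotation_deformation` (-3), `retraction` (-4, terminal
#'   branch retraction), `re_emergence` (-5, extension following a retraction
#'   at the same location), `absent` (0).
#' @examples
#' eventCodes()[["extension"]]
#' @export
eventCodes <- function() {
  c(
    extension = -1L, local_scaling = -2L, rotation_deformation = -3L,
    retraction = -4L, re_emergence = -5L, absent = 0L
  )
}

## Diagnostic codes that make a tree unusable (S4 validity rejects them);
## the rest (bad radius, bad id, missing root) are reported by validateTree()
## on an otherwise constructible object.
.STRUCTURAL_CODES <- c("missing-field", "duplicate-id", "unresolved-parent", "cycle")

## Structural diagnostics on a raw node table; shared by validity checking
## and validateTree(). Returns a data.frame(code, id, message).
.treeDiagnostics <- function(nd) {
  diag <- function(code, id, message) {
    data.frame(code = code, id = id, message = message)
  }
  out <- list()
  if (nrow(nd) == 0L) {
    return(data.frame(code = character(), id = integer(), message = character()))
  }
  if (anyNA(nd)) {
    out <- c(out, list(diag("missing-field", NA_integer_, "NA field value")))
  }
  bad <- nd$id[!is.na(nd$id) & nd$id < 1L]
  for (i in bad) out <- c(out, list(diag("nonpositive-id", i, sprintf("node id %d < 1", i))))
  dup <- unique(nd$id[duplicated(nd$id)])
  for (i in dup) out <- c(out, list(diag("duplicate-id", i, sprintf("duplicate node id %d", i))))
  bad <- nd$id[!is.na(nd$radius) & nd$radius <= 0]
  for (i in bad) {
    out <- c(out, list(diag("nonpositive-radius", i, sprintf("node %d has radius <= 0", i))))
  }
  nonroot <- !is.na(nd$parent) & nd$parent != -1L
  unresolved <- nonroot & !(nd$parent %in% nd$id)
  for (i in nd$id[unresolved]) {
    out <- c(out, list(diag("unresolved-parent", i, sprintf("node %d has unresolved parent", i)))
    )
  }
  if (!any(nd$parent == -1L, na.rm = TRUE)) {
    out <- c(out, list(diag("no-root", NA_integer_, "no root node (parent -1)")))
  }
  ## Cycle detection: follow parent chains with memoised reachability.
  if (length(dup) == 0L && !anyNA(nd$id) && !anyNA(nd$parent)) {
    idx <- match(nd$parent, nd$id) # NA for roots/unresolved
    state <- integer(nrow(nd)) # 0 unseen, 1 in progress, 2 done
    for (s in seq_len(nrow(nd))) {
      v <- s
      path <- integer()
      while (!is.na(v) && state[v] == 0L) {
        state[v] <- 1L
        path <- c(path, v)
        v <- idx[v]
      }
      if (!is.na(v) && state[v] == 1L) {
        out <- c(out, list(diag("cycle", nd$id[v], sprintf("parent cycle through node %d", nd$id[v]))))
        state[path] <- 2L
        break
      }
      state[path] <- 2L
    }
  }
  if (length(out) == 0L) {
    data.frame(code = character(), id = integer(), message = character())
  } else {
    do.call(rbind, out)
  }
}

#' Construct a NeuronTree from a node table
#'
#' @param nodes data.frame (or coercible) with columns id, type, x, y, z,
#'   radius, parent in that order; id, type and parent are stored as integers.
#' @param header character vector of comment lines; lines are prefixed with
#'   "#" if not already.
#' @return A validated [NeuronTree-class].
#' @examples
#' NeuronTree(data.frame(
#'   id = 1L, type = 1L, x = 0, y = 0, z = 0, radius = 5, parent = -1L
#' ))
#' @export
NeuronTree <- function(nodes, header = character()) {
  nodes <- as.data.frame(nodes)
  names(nodes) <- .SWC_COLS
  for (col in c("id", "type", "parent")) nodes[[col]] <- as.integer(nodes[[col]])
  for (col in c("x", "y", "z", "radius")) nodes[[col]] <- as.numeric(nodes[[col]])
  rownames(nodes) <- NULL
  header <- ifelse(grepl("^#", header) | !nzchar(header), header, paste0("#", header))
  new("NeuronTree", nodes = nodes, header = as.character(header))
}

#' @describeIn NeuronTree Node table accessor.
#' @param tree a NeuronTree.
#' @export
swcNodes <- function(tree) tree@nodes

#' @describeIn NeuronTree Header accessor (comment lines, verbatim).
#' @export
swcHeader <- function(tree) tree@header

#' @export
setMethod("length", "NeuronTree", function(x) nrow(x@nodes))

setMethod("show", "NeuronTree", function(object) {
  nd <- object@nodes
  roots <- sum(nd$parent == -1L)
  cat(sprintf(
    "NeuronTree: %d nodes, %d root%s, %d terminal%s, %d branch point%s\n",
    nrow(nd), roots, if (roots == 1L) "" else "s",
    sum(nodeDegrees(object) == 0L), if (sum(nodeDegrees(object) == 0L) == 1L) "" else "s",
    sum(nodeDegrees(object) >= 2L), if (sum(nodeDegrees(object) >= 2L) == 1L) "" else "s"
  ))
  if (length(object@header)) {
    cat(sprintf("  header: %d comment line(s)\n", length(object@header)))
  }
})

#' Number of children of every node
#'
#' Terminals have degree 0, continuation points 1, branch points >= 2
#' (the node-classification vocabulary of compartmental reconstructions).
#'
#' @param tree a [NeuronTree-class].
#' @return Integer vector of child counts, in node order.
#' @export
nodeDegrees <- function(tree) {
  nd <- tree@nodes
  tab <- table(factor(nd$parent[nd$parent != -1L], levels = nd$id))
  as.integer(tab)
}

#' Parse SWC text into a NeuronTree
#'
#' Reads the classic SWC grammar: lines starting with "#" are comments
#' (preserved verbatim, in order, including any trailing `#CHANNELSWC`
#' block); blank lines are ignored; every other line must carry at least 7
#' whitespace-separated numeric tokens -- node id, structure type, x, y, z,
#' radius, parent id. Any run of spaces/tabs separates fields.
#'
#' @param text character vector: either lines, or a single string with
#'   embedded newlines, or a file path when `isPath = TRUE`.
#' @param isPath read `text` as a file path.
#' @return A validated [NeuronTree-class].
#' @examples
#' parseSWC("1 1 0.0 0.0 0.0 5.0 -1")
#' @export
parseSWC <- function(text, isPath = FALSE) {
  if (isPath) text <- readLines(text, warn = FALSE)
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  isComment <- grepl("^\\s*#", text)
  isBlank <- grepl("^\\s*$", text)
  header <- sub("^\\s*", "", text[isComment])
  dataLines <- which(!isComment & !isBlank)
  rows <- vector("list", length(dataLines))
  for (r in seq_along(dataLines)) {
    ln <- dataLines[r]
    tok <- strsplit(trimws(text[ln]), "[ \t]+")[[1]]
    if (length(tok) < 7L) {
      stop(sprintf("line %d: expected 7 fields, found %d", ln, length(tok)))
    }
    vals <- suppressWarnings(as.numeric(tok[1:7]))
    if (anyNA(vals)) {
      stop(sprintf("line %d: non-numeric field '%s'", ln, tok[1:7][is.na(vals)][1]))
    }
    rows[[r]] <- vals
  }
  m <- if (length(rows)) do.call(rbind, rows) else matrix(numeric(), 0, 7)
  nd <- data.frame(
    id = as.integer(m[, 1]), type = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    parent = as.integer(m[, 7])
  )
  diags <- .treeDiagnostics(nd)
  structural <- diags[diags$code %in% .STRUCTURAL_CODES, , drop = FALSE]
  if (nrow(structural)) {
    stop(sprintf("invalid tree structure: %s", paste(structural$message, collapse = "; ")))
  }
  new("NeuronTree", nodes = nd, header = header)
}

#' Read an SWC file
#' @param path file path.
#' @return A [NeuronTree-class].
#' @export
readSWC <- function(path) parseSWC(path, isPath = TRUE)

## Numeric field formatting: integers bare; reals with 6 decimals,
## trailing zeros trimmed. Gives byte-stable round trips for values
## representable at 6 decimals.
.fmtNum <- function(x) {
  out <- character(length(x))
  isInt <- is.finite(x) & x == round(x) & abs(x) < 2^31
  out[isInt] <- sprintf("%d", as.integer(round(x[isInt])))
  if (any(!isInt)) {
    s <- sprintf("%.6f", x[!isInt])
    s <- sub("0+$", "", s)
    s <- sub("\\.$", "", s)
    out[!isInt] <- s
  }
  out
}

## One 7-field SWC line per node.
.formatNodeLines <- function(nd) {
  paste(
    nd$id, nd$type, .fmtNum(nd$x), .fmtNum(nd$y), .fmtNum(nd$z),
    .fmtNum(nd$radius), nd$parent
  )
}

#' Write a NeuronTree as SWC text
#'
#' Emits the header comment lines, then one 7-field line per node in stored
#' order, fields separated by single spaces. `parseSWC(writeSWC(tree))`
#' reproduces the tree field for field (coordinates and radii are written
#' with 6 decimals, trailing zeros trimmed).
#'
#' @param tree a [NeuronTree-class].
#' @param path optional file path; when given the lines are written there
#'   (UTF-8) and returned invisibly.
#' @return Character vector of lines.
#' @export
writeSWC <- function(tree, path = NULL) {
  validObject(tree)
  lines <- c(tree@header, .formatNodeLines(tree@nodes))
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

#' Decompose a tree into its compartments
#'
#' Each non-root node and its parent delimit one frustum: the parent end has
#' the parent's radius, the node end the node's radius. Root nodes yield
#' sphere compartments of their own radius. A degenerate frustum whose two
#' ends coincide in space is treated as a sphere of the larger radius.
#'
#' @param tree a [NeuronTree-class].
#' @return data.frame with one row per node (in node order): `id`; `sphere`
#'   (logical); frustum end points `px, py, pz, pr` (parent) and
#'   `cx, cy, cz, cr` (node); for spheres, both ends are the node and `cr`
#'   carries the effective radius.
#' @examples
#' tr <- parseSWC(c("1 1 0 0 0 2 -1", "2 3 0 0 10 1 1"))
#' compartments(tr)
#' @export
compartments <- function(tree) {
  nd <- tree@nodes
  pidx <- match(nd$parent, nd$id)
  isRoot <- nd$parent == -1L
  px <- ifelse(isRoot, nd$x, nd$x[pidx])
  py <- ifelse(isRoot, nd$y, nd$y[pidx])
  pz <- ifelse(isRoot, nd$z, nd$z[pidx])
  pr <- ifelse(isRoot, nd$radius, nd$radius[pidx])
  degenerate <- !isRoot & px == nd$x & py == nd$y & pz == nd$z
  sphere <- isRoot | degenerate
  cr <- nd$radius
  cr[degenerate] <- pmax(pr[degenerate], nd$radius[degenerate])
  data.frame(
    id = nd$id, sphere = sphere,
    px = px, py = py, pz = pz, pr = pr,
    cx = nd$x, cy = nd$y, cz = nd$z, cr = cr
  )
}

#' Structural diagnostics for a tree
#'
#' Checks every invariant of the SWC node table -- unique positive ids,
#' positive radii, resolvable parents, presence of a root, acyclic parent
#' chains -- and reports violations as structured diagnostics rather than
#' errors.
#'
#' @param tree a [NeuronTree-class], or a raw node data.frame.
#' @return data.frame with columns `code`, `id`, `message`; zero rows iff all
#'   invariants hold.
#' @export
validateTree <- function(tree) {
  nd <- if (is(tree, "NeuronTree")) tree@nodes else as.data.frame(tree)
  .treeDiagnostics(nd)
}
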