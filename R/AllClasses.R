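#' @import methods
NULL

## Column layout shared by every function touching node tables.
.SWC_COLS <- c("id", "type", "x", "y", "z", "radius", "parent")

#' NeuronTree: a classic SWC morphology
#'
#' An S4 container for a digital neuronal reconstruction in the classic SWC
#' sense: an ordered table of nodes, each carrying an integer id, a structure
#' type code (1 = soma, 2 = axon, 3 = dendrite; other integers are preserved),
#' physical x/y/z coordinates in micrometres, a local radius in micrometres and
#' the id of its parent node (-1 for a root). Each non-root node, together with
#' its parent, delimits one frustum compartment; root nodes are modelled as
#' spheres of their own radius so that somatic voxels are claimable during
#' signal extraction.
#'
#' Multiple roots are allowed (one file may hold several trees). Validity
#' requires unique ids >= 1, strictly positive radii, every non-root parent id
#' resolving to another node, and parent chains that terminate at a root
#' (no cycles).
#'
#' @slot nodes data.frame with columns id, type, x, y, z, radius, parent
#'   (one row per node, in file order).
#' @slot header character vector of comment lines (each starting with "#"),
#'   preserved verbatim in order.
#'
#' @seealso [readSWC()], [writeSWC()], [compartments()], [validateTree()]
#' @export
setClass("NeuronTree",
  representation(nodes = "data.frame", header = "character"),
  prototype(
    nodes = data.frame(
      id = integer(), type = integer(), x = numeric(), y = numeric(),
      z = numeric(), radius = numeric(), parent = integer()
    ),
    header = character()
  )
)

setValidity("NeuronTree", function(object) {
  nd <- object@nodes
  if (!identical(names(nd), .SWC_COLS)) {
    return(sprintf(
      "nodes must have columns %s", paste(.SWC_COLS, collapse = ", ")
    ))
  }
  diags <- .treeDiagnostics(nd)
  diags <- diags[diags$code %in% .STRUCTURAL_CODES, , drop = FALSE]
  if (nrow(diags) == 0L) TRUE else paste(diags$message, collapse = "; ")
})

#' ImageStack: a 3-D scalar image volume for one channel
#'
#' Holds one channel of a 3-D acquisition as an integer voxel array with
#' anisotropic physical spacing. Voxel intensities live on the 0-255 (8-bit)
#' or 0-65535 (16-bit) scale. Indexing is 0-based in the coordinate
#' convention: the physical centre of voxel (i, j, k) is
#' ((i + 0.5) sx, (j + 0.5) sy, (k + 0.5) sz) micrometres, in the same frame
#' as SWC coordinates.
#'
#' @slot voxels numeric 3-D array (nx x ny x nz) of non-negative integers.
#' @slot spacing numeric length-3 vector, micrometres per voxel along x, y, z.
#' @slot bitDepth integer, 8 or 16; fixes the admissible intensity range.
#'
#' @seealso [readTIFFStack()], [writeTIFFStack()], [voxelCenter()]
#' @export
setClass("ImageStack",
  representation(voxels = "array", spacing = "numeric", bitDepth = "integer"),
  prototype(voxels = array(0, c(1, 1, 1)), spacing = c(1, 1, 1), bitDepth = 8L)
)

setValidity("ImageStack", function(object) {
  msgs <- character()
  if (length(dim(object@voxels)) != 3L) {
    msgs <- c(msgs, "voxels must be a 3-D array")
  }
  if (length(object@spacing) != 3L || any(object@spacing <= 0)) {
    msgs <- c(msgs, "spacing must be 3 positive values (um/voxel)")
  }
  if (!object@bitDepth %in% c(8L, 16L)) {
    msgs <- c(msgs, "bitDepth must be 8 or 16")
  }
  vmax <- if (identical(object@bitDepth, 16L)) 65535 else 255
  v <- object@voxels
  if (length(v) && (anyNA(v) || min(v) < 0 || max(v) > vmax)) {
    msgs <- c(msgs, sprintf("voxel intensities must lie in [0, %d]", vmax))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' ExtractionConfig: thresholds for multi-channel signal extraction
#'
#' The intensity threshold applied to the primary (membrane/cytosol) channel
#' selects the candidate voxels of each compartment; one threshold per
#' secondary channel then decides which candidates count as signal-positive.
#' "Above threshold" is implemented as intensity >= threshold, so the
#' threshold value itself is considered. The default is 15 on the 0-255
#' scale.
#'
#' @slot primaryThreshold numeric scalar, same intensity scale as the primary
#'   channel.
#' @slot secondaryThresholds numeric vector, one per secondary channel; when
#'   of length zero it is recycled from the primary threshold at use time.
#'
#' @export
setClass("ExtractionConfig",
  representation(primaryThreshold = "numeric", secondaryThresholds = "numeric"),
  prototype(primaryThreshold = 15, secondaryThresholds = numeric())
)

setValidity("ExtractionConfig", function(object) {
  if (length(object@primaryThreshold) != 1L || object@primaryThreshold < 0) {
    return("primaryThreshold must be a single non-negative intensity")
  }
  if (any(object@secondaryThresholds < 0)) {
    return("secondaryThresholds must be non-negative")
  }
  TRUE
})

#' EswcSet: a morphology with per-compartment channel statistics
#'
#' Pairs a [NeuronTree-class] with the (ratio, mean, sd) triple computed for
#' every node and every secondary channel: the fraction of the compartment's
#' candidate voxels whose secondary intensity passes the channel threshold,
#' the mean intensity of those passing voxels, and their population standard
#' deviation. A compartment with ratio near 1 and low sd carries a homogeneous
#' signal; ratio near 0 with high sd marks punctate expression. Written to
#' disk, each node line has 7 + 3C values for C channels (13 values for two
#' channels).
#'
#' @slot tree the underlying [NeuronTree-class].
#' @slot stats numeric matrix, one row per node, 3 columns per channel named
#'   `<channel>.ratio`, `<channel>.mean`, `<channel>.sd`.
#' @slot channels character vector of channel names.
#' @slot thresholds numeric vector of the per-channel secondary thresholds
#'   used (recorded in file headers).
#'
#' @seealso [extractMultichannel()], [writeESWC()], [writeChannelSWC()]
#' @export
setClass("EswcSet",
  representation(
    tree = "NeuronTree", stats = "matrix", channels = "character",
    thresholds = "numeric"
  )
)

setValidity("EswcSet", function(object) {
  C <- length(object@channels)
  msgs <- character()
  if (ncol(object@stats) != 3L * C) {
    msgs <- c(msgs, "stats must have 3 columns per channel")
  }
  if (nrow(object@stats) != nrow(object@tree@nodes)) {
    msgs <- c(msgs, "stats must have one row per node")
  }
  if (C > 0 && nrow(object@stats)) {
    ratios <- object@stats[, 3L * seq_len(C) - 2L, drop = FALSE]
    sds <- object@stats[, 3L * seq_len(C), drop = FALSE]
    if (any(ratios < 0 | ratios > 1)) {
      msgs <- c(msgs, "ratios must lie in [0, 1]")
    }
    if (any(sds < 0)) msgs <- c(msgs, "standard deviations must be >= 0")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' SwcTransition: annotated structural change between two time points
#'
#' The per-node annotation of one transition between consecutive
#' reconstructions of the same neuron. Every node of prev and curr receives
#' exactly one classification: a positive temporal-parent id for stable
#' nodes, or one of the dynamic event codes (see [eventCodes()]): -1 branch
#' extension, -2 local scaling, -3 rotation/deformation, -4 terminal
#' retraction, -5 re-emergence.
#'
#' @slot prev the [NeuronTree-class] at the earlier time point.
#' @slot curr the [NeuronTree-class] at the later time point.
#' @slot events data.frame with columns id, code, type, x, y, z, radius,
#'   parent: one row per node of prev or curr (in curr node order, retracted
#'   nodes appended); geometry columns are zero for retracted nodes.
#'
#' @seealso [annotateTransition()], [consolidateSWCX()]
#' @export
setClass("SwcTransition",
  representation(prev = "NeuronTree", curr = "NeuronTree", events = "data.frame")
)

#' SwcxTable: a time series of morphologies in one table
#'
#' The SWCX consolidation of T reconstructions: one row per node in the union
#' of nodes over all time points. The first 7 columns hold the node's classic
#' SWC fields at time 0 (all but the id zero-filled when the node does not
#' yet exist); each later time point contributes a 7-column block whose first
#' entry is the link field -- a positive temporal-parent id, a dynamic event
#' code, or 0 when the node is absent -- followed by the updated type, x, y,
#' z, radius and parent. With C imaging channels each block (including time 0)
#' additionally carries 3 statistics columns per channel, giving
#' (7 + 3C) x T columns in total.
#'
#' @slot table numeric matrix, one row per union node, laid out as above.
#' @slot timestamps numeric vector of length T; free units (the header does
#'   no unit conversion).
#' @slot channels character vector of channel names (empty for pure SWCX).
#' @slot header character vector of extra comment lines (e.g. global
#'   skeleton-scaling annotations as `# key = value` lines).
#'
#' @seealso [consolidateSWCX()], [extractTimepoint()], [readSWCX()],
#'   [writeSWCX()]
#' @export
setClass("SwcxTable",
  representation(
    table = "matrix", timestamps = "numeric", channels = "character",
    header = "character"
  )
)

setValidity("SwcxTable", function(object) {
  T <- length(object@timestamps)
  C <- length(object@channels)
  if (T < 1L) return("at least one time point required")
  block <- 7L + 3L * C
  if (ncol(object@table) != block * T) {
    return(sprintf(
      "table must have %d columns for %d time points and %d channels",
      block * T, T, C
    ))
  }
  TRUE
})
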