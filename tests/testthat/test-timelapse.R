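simpleTree <- function() {
  parseSWC(c(
    "1 1 0 0 0 2 -1",
    "2 3 0 0 4 1 1",
    "3 3 0 0 8 1 2",
    "4 3 3 0 10 0.8 3",
    "5 3 -3 0 10 0.8 3"
  ))
}

test_that("the classifier implements the event cascade", {
  codes <- eventCodes()
  prev <- list(id = 7L, x = 1, y = 2, z = 3, radius = 0.5)
  parent <- list(x = 1, y = 2, z = 0)
  # identical node: temporal parent link
  expect_identical(classifyEvent(prev, prev), 7L)
  # brand-new node: extension; with history: re-emergence
  expect_identical(classifyEvent(prev, NULL), codes[["extension"]])
  expect_identical(classifyEvent(prev, NULL, everPresent = TRUE), codes[["re_emergence"]])
  # disappearance: retraction
  expect_identical(classifyEvent(NULL, prev), codes[["retraction"]])
  # displacement along the parent axis: local scaling
  moved <- prev
  moved$z <- 4.5
  expect_identical(
    classifyEvent(moved, prev, prevParent = parent),
    codes[["local_scaling"]]
  )
  # radius-only change: local scaling
  fat <- prev
  fat$radius <- 1.5
  expect_identical(classifyEvent(fat, prev, prevParent = parent), codes[["local_scaling"]])
  # sideways displacement: rotation/deformation
  bent <- prev
  bent$x <- 3
  expect_identical(
    classifyEvent(bent, prev, prevParent = parent),
    codes[["rotation_deformation"]]
  )
  expect_error(classifyEvent(NULL, NULL), "absent at both")
})

test_that("identical trees annotate to all-positive self links", {
  tr <- simpleTree()
  trans <- annotateTransition(tr, tr)
  expect_equal(trans@events$code, swcNodes(tr)$id)
  expect_equal(nrow(transitionEvents(trans)), 0L)
})

test_that("a new terminal branch yields exactly its extension codes", {
  prev <- simpleTree()
  nd <- swcNodes(prev)
  branch <- data.frame(
    id = 6:8, type = 3L, x = c(3.5, 4, 4.5), y = 0, z = c(11, 12, 13),
    radius = 0.7, parent = c(4L, 6L, 7L)
  )
  curr <- NeuronTree(rbind(nd[1:4, ], branch, nd[5, ]))
  trans <- annotateTransition(prev, curr)
  ev <- transitionEvents(trans)
  expect_equal(sort(ev$id), 6:8)
  expect_true(all(ev$code == eventCodes()[["extension"]]))
  stable <- trans@events[trans@events$code > 0, ]
  expect_equal(stable$code, stable$id)
})

test_that("an ambiguous explicit correspondence is rejected with the conflict", {
  tr <- simpleTree()
  map <- data.frame(curr = swcNodes(tr)$id, prev = c(1L, 2L, 2L, 4L, 5L))
  expect_error(annotateTransition(tr, tr, map = map), "ambiguous.*2")
})

test_that("nearest-neighbour correspondence matches shifted ids", {
  prev <- simpleTree()
  nd <- swcNodes(prev)
  nd$id <- nd$id + 100L
  nd$parent <- ifelse(nd$parent == -1L, -1L, nd$parent + 100L)
  curr <- NeuronTree(nd)
  trans <- annotateTransition(prev, curr, correspondence = "nearest")
  expect_equal(trans@events$code, swcNodes(prev)$id) # linked by position
  expect_equal(nrow(transitionEvents(trans)), 0L)
})

test_that("consolidation lays out 7 columns per time point", {
  tr <- simpleTree()
  for (T in c(2, 4, 6)) {
    trans <- replicate(T - 1, annotateTransition(tr, tr))
    tab <- consolidateSWCX(trans)
    expect_equal(ncol(swcxMatrix(tab)), 7L * T)
    expect_equal(swcxTimepoints(tab), T)
  }
})

test_that("a no-change series links every node to its own time-0 id", {
  tr <- simpleTree()
  tab <- consolidateSWCX(list(annotateTransition(tr, tr)))
  m <- swcxMatrix(tab)
  expect_equal(m[, 8], m[, 1]) # first link column equals own id
  expect_equal(m[, 9:14], m[, 2:7], ignore_attr = TRUE) # geometry repeated
})

test_that("extension then retraction writes zeros, -1 block, zeros", {
  tr <- generateMorphology(nBranchPoints = 2, seed = 4)
  term <- swcNodes(tr)$id[nodeDegrees(tr) == 0L][1]
  script <- data.frame(
    time = c(1L, 2L), kind = c("extend", "retract"),
    target = c(term, max(swcNodes(tr)$id) + 2L), magnitude = c(4, 0)
  )
  sim <- simulateDynamics(tr, script = script, seed = 9)
  tab <- consolidateSWCX(annotateSeries(sim$trees))
  m <- swcxMatrix(tab)
  newRow <- m[m[, 1] == max(swcNodes(tr)$id) + 1L, ]
  expect_equal(unname(newRow[2:7]), rep(0, 6)) # not yet present at t0
  expect_equal(unname(newRow[8]), eventCodes()[["extension"]])
  expect_equal(unname(newRow[15:21]), rep(0, 7)) # absent after retraction
})

test_that("chained inconsistency in transitions is detected", {
  tr <- simpleTree()
  other <- generateMorphology(nBranchPoints = 1, seed = 2)
  t1 <- annotateTransition(tr, tr)
  t2 <- annotateTransition(other, other)
  expect_error(consolidateSWCX(list(t1, t2)), "chain inconsistency")
})

test_that("per-timepoint extraction reproduces every scripted morphology", {
  for (s in 1:12) {
    tr <- generateMorphology(nBranchPoints = 3, seed = s)
    sim <- simulateDynamics(tr, nTimepoints = 5, seed = s * 7)
    tab <- consolidateSWCX(annotateSeries(sim$trees))
    for (t in seq_along(sim$trees)) {
      expect_trees_equal(extractTimepoint(tab, t - 1L), sim$trees[[t]])
    }
  }
  expect_error(extractTimepoint(consolidateSWCX(annotateSeries(
    simulateDynamics(generateMorphology(seed = 1), nTimepoints = 2, seed = 1)$trees
  )), 5), "out of range")
})

test_that("a retracted-then-reemerged branch is present at t0 and t2 but not t1", {
  tr <- generateMorphology(nBranchPoints = 2, seed = 6)
  term <- swcNodes(tr)$id[nodeDegrees(tr) == 0L][1]
  script <- data.frame(
    time = c(1L, 2L), kind = c("retract", "re-emerge"),
    target = term, magnitude = 0
  )
  sim <- simulateDynamics(tr, script = script, seed = 2)
  tab <- consolidateSWCX(annotateSeries(sim$trees))
  chain <- setdiff(swcNodes(sim$trees[[1]])$id, swcNodes(sim$trees[[2]])$id)
  expect_true(term %in% chain)
  m <- swcxMatrix(tab)
  rows <- m[, 1] %in% chain
  expect_true(all(m[rows, 6] > 0)) # present at t0 (radius > 0)
  expect_true(all(m[rows, 8] == 0)) # absent at t1
  expect_true(all(m[rows, 15] == eventCodes()[["re_emergence"]]))
  expect_trees_equal(extractTimepoint(tab, 2), sim$trees[[3]])
})

test_that("SWCX text round trips and declares its layout in the header", {
  tr <- generateMorphology(nBranchPoints = 2, seed = 8)
  sim <- simulateDynamics(tr, nTimepoints = 4, seed = 3)
  tab <- consolidateSWCX(annotateSeries(sim$trees), timestamps = c(0, 2, 4, 6))
  lines <- writeSWCX(tab)
  T <- swcxTimepoints(tab)
  expect_true(sprintf("# timepoints = %d", T) %in% lines)
  data <- lines[!grepl("^#", lines)]
  expect_true(all(lengths(strsplit(data, " ")) == 7L * T))
  back <- readSWCX(lines)
  expect_equal(swcxMatrix(back), swcxMatrix(tab), ignore_attr = TRUE)
  expect_equal(back@timestamps, c(0, 2, 4, 6))
  expect_identical(writeSWCX(back), lines)
})

test_that("a hand-built two-node two-time table survives round trip token for token", {
  lines <- c(
    "# timepoints = 2",
    "# timestamps = 0 2",
    "1 1 0 0 0 2 -1 1 1 0 0 0 2 -1",
    "2 3 0 0 5 1 1 -2 3 0 0 6.5 1 1"
  )
  tab <- readSWCX(lines)
  expect_identical(writeSWCX(tab), lines)
})

test_that("ragged SWCX rows are a parse error", {
  expect_error(
    readSWCX(c("# timepoints = 2", "1 1 0 0 0 1 -1 1 1 0 0 0 1 -1", "2 3 0 0 1 1 1")),
    "ragged|expected"
  )
})

test_that("positive links always reference a node present at the previous time", {
  for (s in c(3, 5, 13)) {
    tr <- generateMorphology(nBranchPoints = 3, seed = s)
    sim <- simulateDynamics(tr, nTimepoints = 6, seed = s)
    m <- swcxMatrix(sim$gold)
    for (t in seq_len(swcxTimepoints(sim$gold) - 1L)) {
      link <- m[, 7 * t + 1]
      prevPresent <- if (t == 1) m[, 6] > 0 else m[, 7 * (t - 1) + 1] != 0
      prevIds <- m[prevPresent, 1]
      expect_true(all(link[link > 0] %in% prevIds))
    }
    # row count equals the union of node ids over all time points
    expect_equal(nrow(m), length(Reduce(union, lapply(sim$trees, function(x) swcNodes(x)$id))))
    # per time point, the non-absent rows match the static node count
    for (t in seq_along(sim$trees)) {
      present <- if (t == 1) m[, 6] > 0 else m[, 7 * (t - 1) + 1] != 0
      expect_equal(sum(present), length(sim$trees[[t]]))
    }
  }
})

test_that("combined tables carry 3 stats columns per channel per time point", {
  tr <- treeInBox(21, dims = c(48, 48, 48), nBranchPoints = 2)
  sim <- simulateDynamics(tr, nTimepoints = 4, seed = 5)
  tab <- consolidateSWCX(annotateSeries(sim$trees))
  dims <- c(48, 48, 48)
  records <- lapply(sim$trees, function(tp) {
    st <- rasterizeMembrane(tp, dims = dims, intensity = 200)
    asg <- assignVoxels(tp, st, ExtractionConfig(15))
    sec <- paintChannel(asg, signalSpec(swcNodes(tp)$id, "homogeneous"), seed = 8)$stack
    extractMultichannel(tp, st, list(sec), ExtractionConfig(15), channels = "Factin")
  })
  comb <- combineWithChannels(tab, records)
  T <- swcxTimepoints(tab)
  expect_equal(ncol(swcxMatrix(comb)), (7L + 3L) * T) # 40 for T = 4, C = 1
  # absent nodes carry zero statistics
  m <- swcxMatrix(comb)
  for (t in seq_len(T) - 1L) {
    present <- if (t == 0) m[, 6] > 0 else m[, 10 * t + 1] != 0
    statCols <- 10 * t + 8:10
    if (any(!present)) expect_true(all(m[!present, statCols] == 0))
  }
  # time-varying geometry is preserved
  for (t in seq_len(T) - 1L) {
    expect_trees_equal(extractTimepoint(comb, t), sim$trees[[t + 1]])
  }
  # round trip of the combined layout
  back <- readSWCX(writeSWCX(comb))
  expect_equal(swcxMatrix(back), swcxMatrix(comb), ignore_attr = TRUE)
  expect_equal(back@channels, "Factin")
  # node-set mismatch is an alignment error
  expect_error(combineWithChannels(tab, rev(records)), "mismatch|channel")
})

test_that("channel statistics of a growing terminal rise while stable branches stay flat", {
  # emulates cytoskeletal build-up in an elongating branch: the F-actin-like
  # channel is painted brighter in the growing region at each step
  tr0 <- treeInBox(31, dims = c(48, 48, 48), nBranchPoints = 1)
  term <- swcNodes(tr0)$id[nodeDegrees(tr0) == 0L][1]
  script <- data.frame(
    time = 1:3, kind = "extend",
    target = NA_integer_, magnitude = 2.5
  )
  trees <- list(tr0)
  tgt <- term
  for (t in 1:3) {
    script$target[t] <- tgt
    sim1 <- simulateDynamics(trees[[t]], script = script[t, ] |>
      transform(time = 1L), seed = t)
    trees[[t + 1]] <- sim1$trees[[2]]
    tgt <- max(swcNodes(trees[[t + 1]])$id)
  }
  dims <- c(48, 48, 48)
  growingMeans <- numeric()
  stableMeans <- numeric()
  stableNode <- swcNodes(tr0)$id[2]
  for (t in seq_along(trees)) {
    tp <- trees[[t]]
    ids <- swcNodes(tp)$id
    st <- rasterizeMembrane(tp, dims = dims, intensity = 200)
    asg <- assignVoxels(tp, st, ExtractionConfig(15))
    grown <- ids[!(ids %in% swcNodes(tr0)$id)]
    spec <- signalSpec(ids,
      mode = "custom", ratio = 0.9,
      mean = ifelse(ids %in% grown, 80 + 30 * t, 40), sd = 3
    )
    es <- extractMultichannel(tp, st,
      list(paintChannel(asg, spec, seed = t)$stack),
      ExtractionConfig(15),
      channels = "Factin"
    )
    if (length(grown)) {
      growingMeans <- c(growingMeans, mean(eswcStats(es)[match(grown, ids), 2]))
    }
    stableMeans <- c(stableMeans, eswcStats(es)[match(stableNode, ids), 2])
  }
  expect_true(all(diff(growingMeans) > 0)) # builds up while growing
  expect_lt(max(stableMeans) - min(stableMeans), 10) # stable branch stays flat
})
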