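test_that("voxel centres follow the half-voxel convention and invert", {
  expect_equal(voxelCenter(c(0, 0, 0), c(1, 1, 2)), c(0.5, 0.5, 1.0))
  expect_equal(voxelCenter(c(2, 0, 0), c(0.5, 1, 1)), c(1.25, 0.5, 0.5))
  expect_error(voxelCenter(c(5, 0, 0), c(1, 1, 1), dims = c(4, 4, 4)), "out of range")
  # inverse mapping recovers the index
  sp <- c(0.4, 1, 2.5)
  for (idx in list(c(0, 0, 0), c(3, 1, 2), c(7, 5, 0))) {
    ctr <- voxelCenter(idx, sp)
    expect_equal(ctr / sp - 0.5, idx)
  }
})

test_that("frustum membership matches hand geometry", {
  cyl <- data.frame(
    id = 2L, sphere = FALSE, px = 0, py = 0, pz = 0, pr = 2,
    cx = 0, cy = 0, cz = 10, cr = 2
  )
  onAxis <- compartmentContains(cyl, c(0, 0, 5))
  expect_true(onAxis$inside)
  expect_equal(onAxis$ndist, 0)
  expect_false(compartmentContains(cyl, c(3, 0, 5))$inside) # d = 3 > r = 2
  taper <- data.frame(
    id = 2L, sphere = FALSE, px = 0, py = 0, pz = 0, pr = 4,
    cx = 0, cy = 0, cz = 10, cr = 2
  )
  res <- compartmentContains(taper, c(1.5, 0, 7.5)) # r(0.75) = 2.5, d = 1.5
  expect_true(res$inside)
  expect_equal(res$ndist, 0.6)
})

test_that("frustum membership agrees with a dense point-sampling oracle", {
  taper <- data.frame(
    id = 2L, sphere = FALSE, px = 1, py = 2, pz = 0, pr = 3,
    cx = 4, cy = 2, cz = 8, cr = 1
  )
  set.seed(42)
  pts <- cbind(runif(4000, -3, 8), runif(4000, -2, 6), runif(4000, -2, 10))
  got <- compartmentContains(taper, pts)
  p0 <- c(1, 2, 0)
  p1 <- c(4, 2, 8)
  a <- p1 - p0
  for (r in seq_len(nrow(pts))) {
    t0 <- sum((pts[r, ] - p0) * a) / sum(a * a)
    d <- sqrt(sum((pts[r, ] - (p0 + t0 * a))^2))
    want <- t0 >= 0 && t0 <= 1 && d <= 3 + t0 * (1 - 3)
    expect_identical(got$inside[r], want)
  }
})

test_that("sub-threshold stacks assign nothing", {
  tr <- treeInBox(1)
  blank <- ImageStack(array(0, c(24, 24, 24)))
  expect_warning(asg <- assignVoxels(tr, blank, ExtractionConfig(15)), "no voxel")
  expect_equal(nrow(asg), 0L)
  dim <- ImageStack(array(10, c(24, 24, 24))) # uniform but below threshold
  expect_warning(asg2 <- assignVoxels(tr, dim, ExtractionConfig(15)), "no voxel")
  expect_equal(nrow(asg2), 0L)
})

test_that("an isolated frustum claims exactly its interior voxel centres", {
  tr <- parseSWC(c("1 3 6 6 3 1.5 -1", "2 3 6 6 9 1.5 1"))
  st <- rasterizeMembrane(tr, dims = c(12, 12, 12), intensity = 255)
  asg <- assignVoxels(tr, st, ExtractionConfig(15))
  comps <- compartments(tr)
  inAny <- function(p) {
    any(vapply(seq_len(nrow(comps)), function(r) {
      compartmentContains(comps[r, ], p)$inside
    }, logical(1)))
  }
  expect_gt(nrow(asg), 0L)
  for (r in seq_len(nrow(asg))) {
    expect_true(inAny(voxelCenter(unlist(asg[r, c("i", "j", "k")]), c(1, 1, 1))))
  }
  # and conversely: every painted voxel was assigned
  expect_equal(nrow(asg), sum(stackVoxels(st) >= 15))
})

test_that("assignment equals the brute-force oracle on random tree/stack pairs", {
  for (s in 1:8) {
    tr <- treeInBox(s, nBranchPoints = 2)
    st <- rasterizeMembrane(tr, dims = c(24, 24, 24), intensity = 200)
    asg <- assignVoxels(tr, st, ExtractionConfig(15))
    expect_equal(
      canonicalAssignment(asg),
      bruteForceAssign(tr, st, 15),
      ignore_attr = TRUE
    )
  }
})

test_that("candidate voxels are conserved across compartments", {
  tr <- treeInBox(4)
  st <- rasterizeMembrane(tr, dims = c(24, 24, 24), intensity = 200)
  asg <- assignVoxels(tr, st, ExtractionConfig(15))
  expect_equal(sum(table(asg$node)), nrow(asg))
  expect_true(!any(duplicated(asg$voxel))) # a voxel belongs to one compartment
  expect_equal(nrow(asg), sum(stackVoxels(st) >= 15)) # rasterized => all claimed
})

test_that("channel statistics match hand computations", {
  st <- ImageStack(array(c(10, 20, 30, 0), c(4, 1, 1)))
  got <- computeChannelStats(1:3, st, 15)
  expect_equal(got[["ratio"]], 2 / 3)
  expect_equal(got[["mean"]], 25)
  expect_equal(got[["sd"]], 5) # population sd of {20, 30}
  homo <- ImageStack(array(40, c(5, 1, 1)))
  expect_equal(computeChannelStats(1:5, homo, 15), c(ratio = 1, mean = 40, sd = 0))
  expect_equal(computeChannelStats(integer(), homo, 15), c(ratio = 0, mean = 0, sd = 0))
  none <- ImageStack(array(5, c(5, 1, 1)))
  expect_equal(computeChannelStats(1:5, none, 15), c(ratio = 0, mean = 0, sd = 0))
})

test_that("stats invariants hold: range, threshold floor, intensity scaling", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    vals <- sample(0:255, n, replace = TRUE)
    st <- ImageStack(array(vals, c(n, 1, 1)))
    thr <- sample(1:100, 1)
    s1 <- computeChannelStats(seq_len(n), st, thr)
    expect_gte(s1[["ratio"]], 0)
    expect_lte(s1[["ratio"]], 1)
    expect_gte(s1[["sd"]], 0)
    if (s1[["ratio"]] > 0) expect_gte(s1[["mean"]], thr)
    if (sum(vals >= thr) <= 1) expect_equal(s1[["sd"]], 0)
    # scaling intensities and threshold by k scales mean/sd, fixes ratio
    k <- 2
    st2 <- ImageStack(array(vals * k, c(n, 1, 1)), bitDepth = 16L)
    s2 <- computeChannelStats(seq_len(n), st2, thr * k)
    expect_equal(s2[["ratio"]], s1[["ratio"]])
    expect_equal(s2[["mean"]], k * s1[["mean"]])
    expect_equal(s2[["sd"]], k * s1[["sd"]])
  }
})

test_that("full extraction preserves morphology and recovers painted truth", {
  tr <- treeInBox(11, dims = c(30, 30, 30), nBranchPoints = 3)
  st <- rasterizeMembrane(tr, dims = c(30, 30, 30), intensity = 200)
  asg <- assignVoxels(tr, st, ExtractionConfig(15))
  ids <- swcNodes(tr)$id
  p1 <- paintChannel(asg, signalSpec(ids, "homogeneous"), threshold = 15, seed = 2)
  p2 <- paintChannel(asg, signalSpec(ids, "punctate"), threshold = 15, seed = 3)
  es <- extractMultichannel(tr, st, list(p1$stack, p2$stack),
    ExtractionConfig(15),
    channels = c("MT", "Factin")
  )
  expect_equal(swcNodes(eswcTree(es)), swcNodes(tr)) # morphology untouched
  for (p in list(p1, p2)) {
    ch <- if (identical(p, p1)) 1L else 2L
    got <- eswcStats(es)[match(p$truth$node, ids), (3 * ch - 2):(3 * ch), drop = FALSE]
    expect_equal(unname(got[, 1]), p$truth$ratio) # ratio exact
    expect_equal(unname(got[, 2]), p$truth$mean, tolerance = 1e-12)
    expect_equal(unname(got[, 3]), p$truth$sd, tolerance = 1e-12)
  }
})

test_that("homogeneous and punctate presets land on opposite sides of ratio 0.5", {
  tr <- treeInBox(9, dims = c(30, 30, 30))
  st <- rasterizeMembrane(tr, dims = c(30, 30, 30), intensity = 200)
  asg <- assignVoxels(tr, st, ExtractionConfig(15))
  ids <- unique(asg$node)
  homo <- paintChannel(asg, signalSpec(ids, "homogeneous"), seed = 5)
  punct <- paintChannel(asg, signalSpec(ids, "punctate"), seed = 6)
  big <- ids[table(factor(asg$node, levels = ids)) >= 4]
  expect_true(all(homo$truth$ratio[match(big, homo$truth$node)] > 0.5))
  expect_true(all(punct$truth$ratio[match(big, punct$truth$node)] < 0.5))
  # punctate spread exceeds homogeneous spread on a compartment with many voxels
  fat <- parseSWC(c("1 3 10 10 4 3 -1", "2 3 10 10 16 3 1"))
  fatStack <- rasterizeMembrane(fat, dims = c(20, 20, 20), intensity = 200)
  fatAsg <- assignVoxels(fat, fatStack, ExtractionConfig(15))
  fh <- paintChannel(fatAsg, signalSpec(1:2, "homogeneous"), seed = 7)
  fp <- paintChannel(fatAsg, signalSpec(1:2, "punctate"), seed = 8)
  expect_true(all(fh$truth$ratio > 0.5) && all(fp$truth$ratio < 0.5))
  expect_gt(mean(fp$truth$sd), mean(fh$truth$sd))
})

test_that("mismatched stack geometries are rejected", {
  tr <- treeInBox(2)
  st <- rasterizeMembrane(tr, dims = c(24, 24, 24), intensity = 200)
  other <- ImageStack(array(0, c(12, 24, 24)))
  expect_error(extractMultichannel(tr, st, list(other)), "share dimensions")
})
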