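# Fixtures are generated in code, deterministically per seed.

# A morphology guaranteed to fit (including radii) inside dims * spacing,
# found by deterministic seed probing.
treeInBox <- function(seed, dims = c(24, 24, 24), spacing = c(1, 1, 1),
                      nBranchPoints = 2) {
  ext <- dims * spacing
  for (q in 0:199) {
    tr <- generateMorphology(
      nBranchPoints = nBranchPoints, segmentLength = c(3.5, 0.8),
      nodesPerSegment = 2, somaRadius = 1.2, trunkRadius = 0.9,
      origin = ext / 2, seed = seed * 1000 + q
    )
    nd <- swcNodes(tr)
    if (min(nd$x - nd$radius) > 0 && min(nd$y - nd$radius) > 0 &&
      min(nd$z - nd$radius) > 0 &&
      max(nd$x + nd$radius) < ext[1] && max(nd$y + nd$radius) < ext[2] &&
      max(nd$z + nd$radius) < ext[3]) {
      return(tr)
    }
  }
  stop("no fitting tree found")
}

# Independent oracle: every voxel tested against every compartment with
# scalar geometry, smallest normalised radial distance wins, ties to the
# lower node id (compartments visited in increasing id order).
bruteForceAssign <- function(tree, primary, thr) {
  dims <- dim(stackVoxels(primary))
  sp <- stackSpacing(primary)
  comps <- compartments(tree)
  comps <- comps[order(comps$id), ]
  vox <- stackVoxels(primary)
  out <- list()
  for (i in 0:(dims[1] - 1)) {
    for (j in 0:(dims[2] - 1)) {
      for (k in 0:(dims[3] - 1)) {
        if (vox[i + 1, j + 1, k + 1] < thr) next
        p <- c((i + 0.5) * sp[1], (j + 0.5) * sp[2], (k + 0.5) * sp[3])
        best <- Inf
        bid <- NA_integer_
        for (r in seq_len(nrow(comps))) {
          cp <- comps[r, ]
          if (cp$sphere) {
            d <- sqrt(sum((p - c(cp$cx, cp$cy, cp$cz))^2)) / cp$cr
            ins <- d <= 1
          } else {
            a <- c(cp$cx - cp$px, cp$cy - cp$py, cp$cz - cp$pz)
            t0 <- sum((p - c(cp$px, cp$py, cp$pz)) * a) / sum(a * a)
            q <- c(cp$px, cp$py, cp$pz) + t0 * a
            dd <- sqrt(sum((p - q)^2))
            rt <- cp$pr + t0 * (cp$cr - cp$pr)
            ins <- t0 >= 0 && t0 <= 1 && dd <= rt
            d <- dd / rt
          }
          if (ins && d < best) {
            best <- d
            bid <- cp$id
          }
        }
        if (!is.na(bid)) out[[length(out) + 1L]] <- c(i, j, k, bid)
      }
    }
  }
  m <- do.call(rbind, out)
  df <- as.data.frame(if (is.null(m)) matrix(integer(), 0, 4) else m)
  names(df) <- c("i", "j", "k", "node")
  df[order(df$k, df$j, df$i), , drop = FALSE]
}

# Canonicalise an assignment for comparison with the oracle.
canonicalAssignment <- function(asg) {
  a <- asg[order(asg$k, asg$j, asg$i), c("i", "j", "k", "node")]
  rownames(a) <- NULL
  a
}

expect_trees_equal <- function(a, b) {
  expect_equal(swcNodes(a), swcNodes(b))
}

# Path to the installed CLI script (falls back to the source tree under
# pkgload).
cliPath <- function() {
  p <- system.file("exec", "swcxtools", package = "swcx")
  if (!nzchar(p)) p <- file.path(system.file(package = "swcx"), "exec", "swcxtools")
  p
}

runCLI <- function(...) {
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(rscript, c(cliPath(), ...),
    stdout = TRUE, stderr = TRUE
  ))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
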