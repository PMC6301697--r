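test_that("two-lobed lattice is built as specified", {
  g0 <- buildGeometry(100, bridgeCount = 0, dorsomedialFraction = 0.1)
  expect_equal(nrow(g0@cells), 200)
  expect_equal(sum(g0@edges$bridge), 0)
  # no bridges: lobes are disconnected components
  gr0 <- igraph::graph_from_data_frame(g0@edges[, c("from", "to")],
                                       directed = FALSE,
                                       vertices = g0@cells$id)
  expect_equal(igraph::components(gr0)$no, 2)
  # each lobe is itself connected
  comp <- igraph::components(gr0)$membership
  expect_equal(length(unique(comp[g0@cells$lobe == "left"])), 1)

  g5 <- buildGeometry(100, bridgeCount = 5, dorsomedialFraction = 0.1)
  expect_equal(sum(g5@edges$bridge), 5)
  gr5 <- igraph::graph_from_data_frame(g5@edges[, c("from", "to")],
                                       directed = FALSE,
                                       vertices = g5@cells$id)
  expect_equal(igraph::components(gr5)$no, 1)
  # removing the bridges disconnects the graph again
  grCut <- igraph::graph_from_data_frame(
    g5@edges[!g5@edges$bridge, c("from", "to")], directed = FALSE,
    vertices = g5@cells$id)
  expect_equal(igraph::components(grCut)$no, 2)
})

test_that("adjacency is symmetric with no self-edges and labelled bridges", {
  g <- buildGeometry(60, bridgeCount = 3, dorsomedialFraction = 0.15)
  expect_true(all(g@edges$from != g@edges$to))
  expect_true(validObject(g)) # validity enforces symmetry and bridge flags
  lobeOf <- setNames(g@cells$lobe, g@cells$id)
  br <- g@edges[g@edges$bridge, ]
  expect_true(all(lobeOf[br$from] != lobeOf[br$to]))
  expect_equal(sum(g@cells$region == "dorsomedial"), 2 * round(0.15 * 60))
})

test_that("geometry construction rejects impossible arguments", {
  expect_error(buildGeometry(4), "cellsPerLobe")
  expect_error(buildGeometry(100, dorsomedialFraction = 1.5), "Fraction")
  expect_error(buildGeometry(100, bridgeCount = -1), "bridgeCount")
})

test_that("period assignment applies regional offsets", {
  g <- buildGeometry(120, 4, 0.1)
  # zero scatter, no offsets: all frequencies identical
  p0 <- assignPeriods(g, 24, 0, 0, 0, seed = 1)
  expect_true(all(p0$omega == p0$omega[1]))

  # dorsomedial offset shifts that region's sample mean
  p1 <- assignPeriods(g, 24, 1, dorsomedialOffset = -1, seed = 2)
  dm <- g@cells$region == "dorsomedial"
  se <- 1 / sqrt(sum(dm))
  expect_lt(abs(mean(p1$period[dm]) - 23), 2 * se + 2 * 1 / sqrt(sum(dm)))
  expect_lt(abs(mean(p1$period[!dm]) - 24), 3 / sqrt(sum(!dm)))

  # right-lobe offset produces a two-component period distribution
  p2 <- assignPeriods(g, 24, sdPeriod = 0.5, rightLobeOffset = 2, seed = 3)
  right <- g@cells$lobe == "right"
  expect_equal(mean(p2$period[right]) - mean(p2$period[!right]), 2,
               tolerance = 0.2)
  expect_error(assignPeriods(g, 24, 1, rightLobeOffset = -30), "period")
})
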