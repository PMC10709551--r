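test_that("a voxelised tube recovers the analytic cylinder volume", {
  dx <- 1e-4
  R <- 20 * dx
  L <- 100 * dx
  dom <- voxelize(build_tube(R, L), dx)
  expect_equal(n_wet(dom), pi * R^2 * L / dx^3, tolerance = 0.05)
  # caps stamped on single planes with interior fluid neighbours
  io <- dom$iolets
  expect_identical(io$kind, c("velocity_inlet", "pressure_outlet"))
  for (id in io$id) {
    sel <- which(dom$iolet_of == id)
    expect_length(unique(dom$sites[sel, io$axis[io$id == id]]), 1)
  }
  expect_true(all(dom$interior[dom$kind == 2L] > 0))
})

test_that("under-resolved and degenerate geometries are refused", {
  expect_error(voxelize(build_tube(2e-4, 1e-3), 1e-4),
               class = "willisflow_geometry_error")
  expect_error(build_bifurcation(half_angle = 0),
               class = "willisflow_geometry_error")
  expect_error(build_bifurcation(half_angle = 1, l_oblique = 2e-3),
               class = "willisflow_geometry_error")
  # two disjoint tubes in one network: disconnected fluid region
  seg <- dplyr::bind_rows(
    vessel_segment(c(0, 0, 0), c(0, 2e-3, 0), 5e-4, label = "a",
                   flat_start = TRUE, flat_end = TRUE),
    vessel_segment(c(5e-3, 0, 0), c(5e-3, 2e-3, 0), 5e-4, label = "b",
                   flat_start = TRUE, flat_end = TRUE)
  )
  caps <- tibble::tibble(
    label = c("in-a", "out-b"), kind = c("inlet", "outlet"),
    x = c(0, 5e-3), y = c(0, 2e-3), z = c(0, 0),
    axis = 2, sign = c(-1, 1), radius = 5e-4
  )
  expect_error(voxelize(vessel_network(seg, caps), 1e-4),
               class = "willisflow_geometry_error")
})

test_that("the idealised circle of Willis has the study topology and variants", {
  cow <- build_idealized_cow("FULL")
  expect_identical(sum(cow$caps$kind == "inlet"), 3L)
  expect_identical(sum(cow$caps$kind == "outlet"), 6L)
  expect_setequal(cow$caps$label[cow$caps$kind == "inlet"],
                  c("BA", "LICA", "RICA"))
  expect_setequal(cow$caps$label[cow$caps$kind == "outlet"],
                  c("LPCA", "RPCA", "LMCA", "RMCA", "LACA", "RACA"))
  expect_true(all(c("PCoA-L", "PCoA-R") %in% cow$segments$label))
  nr <- build_idealized_cow("NO_PCOA_RIGHT")
  expect_false("PCoA-R" %in% nr$segments$label)
  expect_true("PCoA-L" %in% nr$segments$label)
  expect_identical(nr$caps, cow$caps)  # caps unchanged by the variant
  # removing a vessel strictly shrinks the wet region
  dom_full <- voxelize(cow, 2e-4)
  dom_nl <- voxelize(build_idealized_cow("NO_PCOA_LEFT"), 2e-4)
  expect_lt(n_wet(dom_nl), n_wet(dom_full))
  expect_identical(dim(dom_nl$labels), dim(dom_full$labels))
})

test_that("mirror symmetry of the construction: reflection equals a label swap", {
  # canonicalise (undirected) endpoint order so segments compare cleanly
  canon <- function(seg) {
    seg <- seg[order(seg$label), ]
    for (k in seq_len(nrow(seg))) {
      p1 <- round(unlist(seg[k, c("x1", "y1", "z1")]) * 1e9)
      p2 <- round(unlist(seg[k, c("x2", "y2", "z2")]) * 1e9)
      lex_gt <- p1[1] > p2[1] ||
        (p1[1] == p2[1] && (p1[2] > p2[2] ||
                            (p1[2] == p2[2] && p1[3] > p2[3])))
      if (lex_gt) {
        tmp <- unlist(seg[k, c("x1", "y1", "z1")])
        seg[k, c("x1", "y1", "z1")] <- seg[k, c("x2", "y2", "z2")]
        seg[k, c("x2", "y2", "z2")] <- as.list(tmp)
        seg[k, c("r1", "r2")] <- rev(seg[k, c("r1", "r2")])
        seg[k, c("flat1", "flat2")] <- rev(seg[k, c("flat1", "flat2")])
      }
    }
    seg
  }
  for (net in list(build_idealized_cow("FULL"), build_bifurcation())) {
    mir <- mirror_network(net)
    a <- canon(net$segments)
    b <- canon(mir$segments)
    expect_identical(a$label, b$label)
    for (col in c("x1", "y1", "z1", "x2", "y2", "z2", "r1", "r2")) {
      expect_equal(a[[col]], b[[col]], tolerance = 1e-9,
                   label = paste("segment column", col))
    }
    ca <- net$caps[order(net$caps$label), ]
    cb <- mir$caps[order(mir$caps$label), ]
    expect_identical(ca$label, cb$label)
    for (col in c("x", "y", "z", "radius")) {
      expect_equal(ca[[col]], cb[[col]], tolerance = 1e-9,
                   label = paste("cap column", col))
    }
    expect_identical(ca$kind, cb$kind)
  }
  # the two one-sided variants are mirror images of each other
  l <- voxelize(build_idealized_cow("NO_PCOA_LEFT"), 2e-4)
  r <- voxelize(build_idealized_cow("NO_PCOA_RIGHT"), 2e-4)
  expect_identical(n_wet(l), n_wet(r))
})

test_that("inlet wall distances and parabolic weights reconstruct Poiseuille", {
  dom <- voxelize(build_tube(4e-4, 1.6e-3), 1e-4)
  d <- inlet_wall_distance(dom, "in")
  sel <- which(dom$iolet_of == 1)
  xz <- cbind(dom$origin[1] + (dom$sites[sel, 1] - 0.5) * dom$dx,
              dom$origin[3] + (dom$sites[sel, 3] - 0.5) * dom$dx)
  r <- sqrt(xz[, 1]^2 + xz[, 2]^2)
  # centre site reaches ~R from the wall, wall-adjacent sites ~dx
  expect_equal(max(d), 4e-4, tolerance = 0.15)
  expect_equal(min(d), dom$dx, tolerance = 0.5)
  expect_equal(d[which.min(r)], max(d))
  # 90-degree rotation of the circular cap permutes sites but not distances
  key <- paste(round(xz[, 1] / dom$dx, 1), round(xz[, 2] / dom$dx, 1))
  rkey <- paste(round(-xz[, 2] / dom$dx, 1), round(xz[, 1] / dom$dx, 1))
  idx <- match(rkey, key)
  expect_false(anyNA(idx))
  expect_equal(d[idx], d, tolerance = 1e-12)
  # weights: endpoints and the parabolic profile in the radial coordinate
  w <- inlet_weights(d)
  expect_equal(w[which.max(d)], 1)
  expect_equal(min(w), 1 - (1 - min(d) / max(d))^2, tolerance = 1e-12)
  expect_true(all(w >= 0 & w <= 1))
})

test_that("parabolic weights on a well-resolved circular cap follow 1 - (r/R)^2", {
  dom <- poiseuille_fixture()$domain   # 32 sites per diameter
  R <- 8e-4
  d <- inlet_wall_distance(dom, "in")
  w <- inlet_weights(d)
  sel <- which(dom$iolet_of == 1)
  x <- dom$origin[1] + (dom$sites[sel, 1] - 0.5) * dom$dx
  z <- dom$origin[3] + (dom$sites[sel, 3] - 0.5) * dom$dx
  r <- sqrt(x^2 + z^2)
  parab <- pmax(1 - (r / R)^2, 0)
  # agreement to staircase (first-order in dx/R) accuracy
  expect_lt(max(abs(w - parab)), 0.2)
  expect_lt(mean(abs(w - parab)), 0.06)
  expect_gt(stats::cor(w, parab), 0.995)
})

test_that("voxel masks round-trip through the text exchange format", {
  dom <- voxelize(build_tube(4e-4, 1.2e-3), 1e-4)
  path <- withr::local_tempfile(fileext = ".txt")
  export_voxel_mask(dom, path)
  back <- import_voxel_mask(path)
  expect_identical(back$labels, dom$labels)
  expect_identical(back$iolet_id, dom$iolet_id)
  expect_equal(back$dx, dom$dx)
  expect_equal(back$origin, dom$origin)
})
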