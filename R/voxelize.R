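# Voxelisation of vessel networks to classified lattices, plus the simple
# box domains used for analytic validation (periodic box, closed box,
# Couette channel). Site centres sit at origin + (ijk - 0.5) * dx with
# 1-based integer indices; every wet site is guaranteed a full shell of
# classified neighbours by a >= 1 site solid padding (or periodicity).

D3Q19_DIRS <- function() velocity_set()$directions

#' Number of wet (fluid + iolet) sites in a domain
#' @param domain A `voxel_domain`.
#' @return Integer site count.
#' @export
n_wet <- function(domain) nrow(domain$sites)

#' @export
print.voxel_domain <- function(x, ...) {
  cat(sprintf(
    "<voxel_domain> %d x %d x %d grid, dx = %g m, %d wet sites (%d fluid), %d iolets\n",
    x$shape[1], x$shape[2], x$shape[3], x$dx,
    n_wet(x), sum(x$kind == 0L), nrow(x$iolets)
  ))
  invisible(x)
}

# Internal constructor: derives the site list, neighbour codes, interior
# neighbours, inlet weights and connectivity from a labelled grid.
# labels: 0 solid, 1 fluid, 2 inlet, 3 outlet; iolet_id parallel (0 = none).
# iolets: tibble(id, label, kind, axis, sign, x, y, z, radius[, dirx, diry, dirz])
new_voxel_domain <- function(labels, iolet_id, dx, origin, iolets,
                             periodic = c(FALSE, FALSE, FALSE),
                             check_connectivity = TRUE,
                             compute_weights = TRUE) {
  shape <- dim(labels)
  wet_lin <- which(labels > 0L)
  if (length(wet_lin) == 0) abort_geometry("Domain contains no wet sites.")
  sites <- arrayInd(wet_lin, shape)
  n <- nrow(sites)
  site_id <- array(0L, shape)
  site_id[wet_lin] <- seq_len(n)
  kind <- labels[wet_lin] - 1L          # 0 fluid, 1 inlet, 2 outlet
  iolet_of <- iolet_id[wet_lin]

  ax_of <- rep(NA_integer_, n)
  sg_of <- rep(NA_real_, n)
  if (nrow(iolets) > 0) {
    pos <- iolet_of > 0L
    ax_of[pos] <- as.integer(iolets$axis[iolet_of[pos]])
    sg_of[pos] <- iolets$sign[iolet_of[pos]]
  }

  dirs <- D3Q19_DIRS()
  nx <- shape[1]; ny <- shape[2]
  neigh <- matrix(0L, 19, n)
  for (i in 1:19) {
    tgt <- sweep(sites, 2, dirs[i, ], "+")
    for (a in 1:3) {
      if (periodic[a]) tgt[, a] <- ((tgt[, a] - 1L) %% shape[a]) + 1L
    }
    inb <- tgt[, 1] >= 1 & tgt[, 1] <= shape[1] &
           tgt[, 2] >= 1 & tgt[, 2] <= shape[2] &
           tgt[, 3] >= 1 & tgt[, 3] <= shape[3]
    code <- rep(0L, n)
    lin <- tgt[inb, 1] + (tgt[inb, 2] - 1L) * nx + (tgt[inb, 3] - 1L) * nx * ny
    code[inb] <- site_id[lin]
    dry <- code == 0L
    if (any(dry)) {
      code[dry] <- -1L
      # iolet sites: links through the cap plane resolve against the iolet
      cap <- which(dry & kind > 0L)
      if (length(cap) > 0) {
        cdotn <- dirs[i, ax_of[cap]] * sg_of[cap]
        exterior <- cap[cdotn > 0]
        code[exterior] <- -(1L + kind[exterior])  # -2 inlet, -3 outlet
      }
    }
    neigh[i, ] <- code
  }

  # interior neighbour (one site inward along the cap normal) for outlets
  interior <- integer(n)
  outs <- which(kind == 2L)
  if (length(outs) > 0) {
    for (s in outs) {
      inward <- -sg_of[s] * axis_unit(ax_of[s])
      d <- which(dirs[, 1] == inward[1] & dirs[, 2] == inward[2] &
                 dirs[, 3] == inward[3])
      interior[s] <- neigh[d, s]
    }
    if (any(interior[outs] <= 0)) {
      abort_geometry("An outlet site has no wet interior neighbour along the cap normal.")
    }
  }

  if (check_connectivity) {
    comp <- cpp_components(neigh)
    if (max(comp) > 1L) {
      sizes <- sort(tabulate(comp), decreasing = TRUE)
      abort_geometry(sprintf(
        "Fluid region is disconnected: %d components of sizes %s.",
        max(comp), paste(sizes, collapse = ", ")
      ))
    }
  }

  # default flow/velocity directions for iolets
  if (nrow(iolets) > 0) {
    if (!("dirx" %in% names(iolets))) {
      iolets$dirx <- NA_real_; iolets$diry <- NA_real_; iolets$dirz <- NA_real_
    }
    for (k in seq_len(nrow(iolets))) {
      if (is.na(iolets$dirx[k])) {
        # inlets: inward normal (prescribed velocity direction and positive
        # inflow); outlets: outward normal (positive outflow)
        s <- if (iolets$kind[k] == "inlet") -iolets$sign[k] else iolets$sign[k]
        d <- s * axis_unit(iolets$axis[k])
        iolets$dirx[k] <- d[1]; iolets$diry[k] <- d[2]; iolets$dirz[k] <- d[3]
      }
    }
    iolets$kind <- ifelse(iolets$kind == "inlet", "velocity_inlet",
                   ifelse(iolets$kind == "outlet", "pressure_outlet", iolets$kind))
    iolets$n_sites <- vapply(iolets$id, function(id) sum(iolet_of == id), integer(1))
    if (any(iolets$n_sites == 0)) {
      abort_geometry(sprintf(
        "Iolet(s) %s have no lattice sites.",
        paste(iolets$label[iolets$n_sites == 0], collapse = ", ")
      ))
    }
  } else {
    iolets <- tibble::tibble(
      id = integer(), label = character(), kind = character(),
      axis = integer(), sign = numeric(), x = numeric(), y = numeric(),
      z = numeric(), radius = numeric(), dirx = numeric(), diry = numeric(),
      dirz = numeric(), n_sites = integer()
    )
  }

  dom <- structure(
    list(
      shape = shape, dx = dx, origin = origin,
      labels = labels, iolet_id = iolet_id,
      sites = sites, site_id = site_id,
      kind = kind, iolet_of = iolet_of,
      weight = rep(1, n), neigh = neigh, interior = interior,
      iolets = iolets, periodic = periodic
    ),
    class = "voxel_domain"
  )

  # parabolic-approximation inlet weights from in-plane wall distance
  if (compute_weights) {
    for (k in which(dom$iolets$kind == "velocity_inlet")) {
      idk <- dom$iolets$id[k]
      sel <- dom$iolet_of == idk
      d <- inlet_wall_distance(dom, idk)
      dom$weight[sel] <- inlet_weights(d)
    }
  }
  dom
}

#' Voxelise a vessel network
#'
#' Classifies a regular lattice against the union of the network's capsule
#' segments: a site is fluid iff its centre lies inside the union, cap
#' layers are stamped as inlet/outlet planes, the domain is padded with at
#' least one solid layer, and full 19-neighbourhood connectivity of the wet
#' region is verified. Refuses geometries whose narrowest vessel is
#' resolved by fewer than 3 sites in radius.
#'
#' @param network A `vessel_network`.
#' @param dx Lattice spacing in metres.
#' @param pad Number of solid padding layers (default 2).
#' @return A `voxel_domain`.
#' @export
#' @examples
#' dom <- voxelize(build_tube(radius = 6e-4, length = 2e-3), dx = 1e-4)
#' dom
voxelize <- function(network, dx, pad = 2L) {
  stopifnot(inherits(network, "vessel_network"))
  seg <- network$segments
  rmin <- min(seg$r1, seg$r2)
  if (rmin < 3 * dx) {
    abort_geometry(sprintf(
      "Narrowest vessel radius %.3g m is under-resolved at dx = %.3g m; need dx <= %.3g m (radius >= 3 dx).",
      rmin, dx, rmin / 3
    ))
  }
  rmax_all <- max(seg$r1, seg$r2)
  lo <- pmin(
    apply(seg[, c("x1", "y1", "z1")], 2, min),
    apply(seg[, c("x2", "y2", "z2")], 2, min)
  ) - rmax_all
  hi <- pmax(
    apply(seg[, c("x1", "y1", "z1")], 2, max),
    apply(seg[, c("x2", "y2", "z2")], 2, max)
  ) + rmax_all
  ilo <- unname(floor(lo / dx) - pad)
  ihi <- unname(ceiling(hi / dx) + pad)
  origin <- ilo * dx
  shape <- as.integer(ihi - ilo)
  labels <- array(0L, shape)

  axc <- lapply(1:3, function(a) origin[a] + (seq_len(shape[a]) - 0.5) * dx)

  for (si in seq_len(nrow(seg))) {
    s <- seg[si, ]
    a <- c(s$x1, s$y1, s$z1); b <- c(s$x2, s$y2, s$z2)
    rmax <- max(s$r1, s$r2)
    crange <- lapply(1:3, function(ax) {
      which(axc[[ax]] >= min(a[ax], b[ax]) - rmax - dx &
            axc[[ax]] <= max(a[ax], b[ax]) + rmax + dx)
    })
    ncr <- vapply(crange, length, integer(1))
    if (any(ncr == 0)) next
    px <- rep(axc[[1]][crange[[1]]], times = ncr[2] * ncr[3])
    py <- rep(rep(axc[[2]][crange[[2]]], each = ncr[1]), times = ncr[3])
    pz <- rep(axc[[3]][crange[[3]]], each = ncr[1] * ncr[2])
    v <- b - a
    L2 <- sum(v * v)
    traw <- ((px - a[1]) * v[1] + (py - a[2]) * v[2] + (pz - a[3]) * v[3]) / L2
    tc <- pmin(1, pmax(0, traw))
    qx <- a[1] + tc * v[1]; qy <- a[2] + tc * v[2]; qz <- a[3] + tc * v[3]
    d2 <- (px - qx)^2 + (py - qy)^2 + (pz - qz)^2
    rt <- s$r1 + (s$r2 - s$r1) * tc
    member <- d2 <= rt^2
    if (s$flat1) member <- member & traw >= 0
    if (s$flat2) member <- member & traw <= 1
    if (any(member)) {
      idx <- arrayInd(which(member), ncr)
      lin <- crange[[1]][idx[, 1]] +
        (crange[[2]][idx[, 2]] - 1L) * shape[1] +
        (crange[[3]][idx[, 3]] - 1L) * shape[1] * shape[2]
      labels[lin] <- 1L
    }
  }

  # stamp inlet/outlet cap layers
  iolet_id <- array(0L, shape)
  caps <- network$caps
  caps$id <- seq_len(nrow(caps))
  for (k in seq_len(nrow(caps))) {
    cp <- caps[k, ]
    m <- as.integer(cp$axis)
    coords <- axc[[m]]
    inside <- which(cp$sign * (coords - cp[[c("x", "y", "z")[m]]]) < 0)
    if (length(inside) == 0) abort_geometry(sprintf("Cap '%s' lies outside the grid.", cp$label))
    layer <- inside[which.min(abs(coords[inside] - cp[[c("x", "y", "z")[m]]]))]
    others <- setdiff(1:3, m)
    cc <- c(cp$x, cp$y, cp$z)
    ga <- axc[[others[1]]]; gb <- axc[[others[2]]]
    da <- rep(ga - cc[others[1]], times = length(gb))
    db <- rep(gb - cc[others[2]], each = length(ga))
    inplane <- matrix(sqrt(da^2 + db^2) <= cp$radius + 0.6 * dx,
                      length(ga), length(gb))
    sl <- switch(m,
      labels[layer, , ],
      labels[, layer, ],
      labels[, , layer]
    )
    mark <- sl == 1L & inplane
    sl[mark] <- if (cp$kind == "inlet") 2L else 3L
    io_sl <- switch(m,
      iolet_id[layer, , ],
      iolet_id[, layer, ],
      iolet_id[, , layer]
    )
    io_sl[mark] <- cp$id
    if (m == 1) { labels[layer, , ] <- sl; iolet_id[layer, , ] <- io_sl }
    if (m == 2) { labels[, layer, ] <- sl; iolet_id[, layer, ] <- io_sl }
    if (m == 3) { labels[, , layer] <- sl; iolet_id[, , layer] <- io_sl }
  }

  dom <- new_voxel_domain(labels, iolet_id, dx, origin, caps)
  dom$network <- network
  dom
}

#' Fully periodic box domain
#'
#' Every site fluid, all three axes periodic; used for shear-wave and
#' conservation validation.
#'
#' @param shape Length-3 integer grid shape.
#' @param dx Lattice spacing (m).
#' @return A `voxel_domain`.
#' @export
build_periodic_box <- function(shape, dx) {
  labels <- array(1L, shape)
  new_voxel_domain(labels, array(0L, shape), dx, c(0, 0, 0),
                   tibble::tibble(), periodic = c(TRUE, TRUE, TRUE))
}

#' Closed box domain
#'
#' Fluid interior fully enclosed by solid walls; conserves mass exactly
#' under bounce-back.
#'
#' @param shape Length-3 integer shape of the *fluid* interior.
#' @param dx Lattice spacing (m).
#' @return A `voxel_domain`.
#' @export
build_closed_box <- function(shape, dx) {
  full <- as.integer(shape + 2L)
  labels <- array(0L, full)
  labels[2:(full[1] - 1), 2:(full[2] - 1), 2:(full[3] - 1)] <- 1L
  new_voxel_domain(labels, array(0L, full), dx, c(0, 0, 0), tibble::tibble())
}

#' Planar Couette channel
#'
#' A channel periodic in x and y, bounded below by a static wall and above
#' by a tangentially moving wall (implemented as a velocity iolet whose
#' direction is in-plane, weight 1 everywhere). The analytic steady state
#' is a linear shear profile with wall stress `rho * nu * U / H`,
#' `H = nz * dx` the gap between the two halfway wall planes.
#'
#' @param nx,ny,nz Fluid extents; `nz` is the number of fluid layers across
#'   the gap.
#' @param dx Lattice spacing (m).
#' @param direction Length-3 unit vector of the moving-wall velocity
#'   (default +x).
#' @return A `voxel_domain` with a single iolet labelled `"lid"`.
#' @export
build_couette_channel <- function(nx = 4, ny = 4, nz = 16, dx = 1e-4,
                                  direction = c(1, 0, 0)) {
  shape <- as.integer(c(nx, ny, nz + 2L))
  labels <- array(0L, shape)
  labels[, , 2:(nz + 1)] <- 1L
  labels[, , nz + 1] <- 2L   # moving lid layer
  iolet_id <- array(0L, shape)
  iolet_id[, , nz + 1] <- 1L
  direction <- direction / sqrt(sum(direction^2))
  iolets <- tibble::tibble(
    id = 1L, label = "lid", kind = "inlet", axis = 3L, sign = 1,
    x = nx * dx / 2, y = ny * dx / 2, z = (nz + 0.5) * dx,
    radius = max(nx, ny) * dx,
    dirx = direction[1], diry = direction[2], dirz = direction[3]
  )
  new_voxel_domain(labels, iolet_id, dx, c(0, 0, 0), iolets,
                   periodic = c(TRUE, TRUE, FALSE), compute_weights = FALSE)
}

#' In-plane wall distance for an inlet cap
#'
#' For every site of an inlet plane, the Euclidean distance (metres) from
#' the site centre to the nearest solid site centre *within the cap plane*.
#' This is the input to the parabolic weighting that reconstructs a
#' Poiseuille profile on a circular cap.
#'
#' @param domain A `voxel_domain`.
#' @param iolet Iolet id (integer) or label.
#' @return Numeric vector of distances, ordered as the iolet's sites appear
#'   in the domain site list.
#' @export
inlet_wall_distance <- function(domain, iolet) {
  io <- resolve_iolet(domain, iolet)
  sel <- which(domain$iolet_of == io$id)
  if (length(sel) == 0) abort_geometry("Inlet has no sites.")
  m <- as.integer(io$axis)
  others <- setdiff(1:3, m)
  sites <- domain$sites[sel, , drop = FALSE]
  layer <- unique(sites[, m])
  if (length(layer) != 1) abort_geometry("Inlet sites do not form a single grid plane.")
  sl <- switch(m,
    domain$labels[layer, , ],
    domain$labels[, layer, ],
    domain$labels[, , layer]
  )
  a <- sites[, others[1]]; b <- sites[, others[2]]
  pad <- ceiling(io$radius / domain$dx) + 3
  arange <- max(1, min(a) - pad):min(dim(sl)[1], max(a) + pad)
  brange <- max(1, min(b) - pad):min(dim(sl)[2], max(b) + pad)
  sub <- sl[arange, brange, drop = FALSE]
  solid <- which(sub == 0L, arr.ind = TRUE)
  if (nrow(solid) == 0) abort_geometry("Inlet plane has no bounding wall in range.")
  sa <- arange[solid[, 1]]; sb <- brange[solid[, 2]]
  d <- vapply(seq_along(a), function(j) {
    sqrt(min((sa - a[j])^2 + (sb - b[j])^2))
  }, numeric(1))
  d * domain$dx
}

#' Parabolic inlet weights from wall distances
#'
#' `w(s) = 1 - (1 - d(s)/d_max)^2`: zero at the wall, one at the site
#' furthest from the wall. On a circular cap, substituting the radial wall
#' distance `d = R - r` gives `w = 1 - (r/R)^2`, the Poiseuille parabola.
#'
#' @param distances Non-negative distances (any consistent unit).
#' @return Weights in `[0, 1]`.
#' @export
inlet_weights <- function(distances) {
  dmax <- max(distances)
  if (dmax <= 0) abort_geometry("All inlet sites touch the wall; cap is degenerate.")
  1 - (1 - distances / dmax)^2
}

resolve_iolet <- function(domain, iolet) {
  io <- domain$iolets
  k <- if (is.character(iolet)) match(iolet, io$label) else match(iolet, io$id)
  if (is.na(k)) abort_config(sprintf("Unknown iolet '%s'.", as.character(iolet)))
  io[k, ]
}
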