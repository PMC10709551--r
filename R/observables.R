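# Observables: per-outlet volumetric flow rate, stroke-to-healthy flow
# ratios, cycle averages, velocity-magnitude fields and wall shear stress.

#' Volumetric flow rate through an iolet plane
#'
#' `Q = dx^2 * sum_s u_n(s)` over the sites of a planar cap, converted to
#' m^3/s. The flow direction is the iolet's stored direction: the inward
#' normal for inlets (positive inflow) and the outward normal for outlets
#' (positive outflow).
#'
#' @param f 19 x n population matrix.
#' @param domain A `voxel_domain`.
#' @param iolet Iolet id or label.
#' @param units A [lattice_units()] object.
#' @return Flow rate in m^3/s.
#' @export
outlet_flow_rate <- function(f, domain, iolet, units) {
  io <- resolve_iolet(domain, iolet)
  sel <- which(domain$iolet_of == io$id)
  m <- macroscopics(f[, sel, drop = FALSE])
  dirv <- c(io$dirx, io$diry, io$dirz)
  sum(colSums(m$u * dirv)) * units$dx^2 * units$velocity
}

#' Velocity magnitude field
#'
#' `|u|` in m/s per wet site, with the domain maximum attached as the
#' `"max"` attribute.
#'
#' @param f 19 x n population matrix.
#' @param domain A `voxel_domain`.
#' @param units A [lattice_units()] object.
#' @return A tibble with site indices, physical coordinates and
#'   `speed_m_s`.
#' @export
velocity_magnitude <- function(f, domain, units) {
  m <- macroscopics(f)
  sp <- sqrt(colSums(m$u^2)) * units$velocity
  out <- tibble::tibble(
    i = domain$sites[, 1], j = domain$sites[, 2], k = domain$sites[, 3],
    x = domain$origin[1] + (domain$sites[, 1] - 0.5) * domain$dx,
    y = domain$origin[2] + (domain$sites[, 2] - 0.5) * domain$dx,
    z = domain$origin[3] + (domain$sites[, 3] - 0.5) * domain$dx,
    speed_m_s = sp
  )
  attr(out, "max") <- max(sp)
  out
}

#' Time average over one cardiac cycle
#'
#' Trapezoidal time-mean of a sampled series over the window
#' `[t0 + (cycle-1) T, t0 + cycle T]`; the window endpoints are linearly
#' interpolated so a full cycle is integrated exactly.
#'
#' @param time,value Sample times (s) and values (equal length).
#' @param period Cycle duration T, s.
#' @param cycle Which cycle to average (1-based).
#' @param t0 Time origin of cycle 1, s.
#' @return The scalar time-mean.
#' @export
cycle_average <- function(time, value, period, cycle = 1, t0 = 0) {
  a <- t0 + (cycle - 1) * period
  b <- t0 + cycle * period
  if (min(time) > a + 1e-12 || max(time) < b - 1e-12) {
    abort_parameter(sprintf(
      "Series [%g, %g] s does not span the requested cycle [%g, %g] s.",
      min(time), max(time), a, b
    ))
  }
  inside <- time > a & time < b
  tt <- c(a, time[inside], b)
  vv <- c(stats::approx(time, value, a)$y, value[inside],
          stats::approx(time, value, b)$y)
  sum(diff(tt) * (head(vv, -1) + tail(vv, -1)) / 2) / (b - a)
}

#' Stroke-to-healthy flow-ratio series
#'
#' Pointwise ratio of window-averaged flow series, per outlet. Samples
#' where the smoothed healthy flow is within `mask_frac` of zero (relative
#' to its own maximum magnitude) are masked rather than divided.
#'
#' @param stroke,healthy Series tibbles with columns `time_s`, `iolet`,
#'   `q_m3s` on identical time stamps (e.g. from `run$series`).
#' @param window_s Smoothing window in seconds (default: no smoothing).
#' @param mask_frac Relative healthy-flow threshold below which the ratio
#'   is masked (default 0.02).
#' @return A tibble `time_s`, `iolet`, `q_stroke`, `q_healthy`, `ratio`,
#'   `masked`.
#' @export
flow_ratio <- function(stroke, healthy, window_s = NULL, mask_frac = 0.02) {
  if (!identical(dim(stroke), dim(healthy)) ||
      !isTRUE(all.equal(stroke$time_s, healthy$time_s)) ||
      !identical(stroke$iolet, healthy$iolet)) {
    abort_config("Stroke and healthy series must share time stamps and iolets.")
  }
  smooth1 <- function(x, w) {
    if (w <= 1) return(x)
    y <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
    y[is.na(y)] <- x[is.na(y)]
    y
  }
  dts <- diff(sort(unique(stroke$time_s)))
  w <- if (is.null(window_s) || length(dts) == 0) 1 else
    max(1, round(window_s / stats::median(dts)))
  if (w %% 2 == 0) w <- w + 1
  out <- dplyr::group_by(
    tibble::tibble(
      time_s = stroke$time_s, iolet = stroke$iolet,
      q_stroke = stroke$q_m3s, q_healthy = healthy$q_m3s
    ),
    .data$iolet
  )
  out <- dplyr::mutate(out,
    qs = smooth1(.data$q_stroke, w),
    qh = smooth1(.data$q_healthy, w),
    masked = abs(.data$qh) < mask_frac * max(abs(.data$qh)),
    ratio = ifelse(.data$masked, NA_real_, .data$qs / .data$qh)
  )
  dplyr::select(dplyr::ungroup(out), "time_s", "iolet", "q_stroke",
                "q_healthy", "ratio", "masked")
}

# --- wall shear stress -------------------------------------------------------

# 3x3x3 box smoothing of the solid indicator; outside the grid counts as
# solid for closed axes and wraps for periodic ones.
smooth_solid_indicator <- function(domain) {
  a <- (domain$labels == 0L) * 1
  d <- dim(a)
  p <- array(1, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
  for (ax in 1:3) {
    if (domain$periodic[ax]) {
      idx_lo <- slice.index(p, ax) == 1
      idx_hi <- slice.index(p, ax) == d[ax] + 2
      src_hi <- slice.index(p, ax) == d[ax] + 1
      src_lo <- slice.index(p, ax) == 2
      p[idx_lo] <- p[src_hi]
      p[idx_hi] <- p[src_lo]
    }
  }
  B <- array(0, d)
  for (ox in 0:2) for (oy in 0:2) for (oz in 0:2) {
    B <- B + p[ox + seq_len(d[1]), oy + seq_len(d[2]), oz + seq_len(d[3])]
  }
  B / 27
}

#' Wall shear stress field
#'
#' Estimates the deviatoric fluid stress from the non-equilibrium
#' populations,
#' \eqn{\sigma_{\alpha\beta} = -(1 - 1/(2\tau)) \sum_i c_{i\alpha}
#' c_{i\beta} (f_i - f_i^{eq})}, at every fluid site with at least one
#' face-adjacent solid neighbour, projects the traction
#' \eqn{t = \sigma \hat n} onto the wall tangent plane, and reports its
#' magnitude in pascals. The outward normal \eqn{\hat n} is the normalised
#' central-difference gradient of a 3x3x3 box-smoothed solid indicator,
#' which is robust on staircase walls. Elements with a degenerate normal
#' (isolated voxels) are skipped and counted in the `"skipped"` attribute.
#'
#' @param f 19 x n population matrix.
#' @param tau Relaxation time used in the run.
#' @param domain A `voxel_domain`.
#' @param units A [lattice_units()] object.
#' @param extrapolate If `TRUE` (default) the stress tensor is linearly
#'   extrapolated half a lattice link towards the wall along the dominant
#'   normal direction before forming the traction, compensating the
#'   half-site offset between wall-adjacent centres and the bounce-back
#'   wall plane. `FALSE` evaluates the tensor at the site centre.
#' @return A tibble with site indices, coordinates, normal components and
#'   `wss_pa`.
#' @export
wss_field <- function(f, tau, domain, units, extrapolate = TRUE) {
  if (tau <= 0.5) abort_parameter("`tau` must exceed 1/2.")
  vs <- velocity_set()
  face <- 2:7   # the six axis directions in the stencil ordering
  wall_adj <- which(domain$kind == 0L &
                    colSums(domain$neigh[face, , drop = FALSE] == -1L) > 0)
  if (length(wall_adj) == 0) {
    out <- tibble::tibble(i = integer(), j = integer(), k = integer(),
                          x = numeric(), y = numeric(), z = numeric(),
                          nx = numeric(), ny = numeric(), nz = numeric(),
                          wss_pa = numeric())
    attr(out, "skipped") <- 0L
    return(out)
  }
  stress6 <- function(idx) {
    fs <- f[, idx, drop = FALSE]
    m <- macroscopics(fs)
    fneq <- fs - equilibrium(m$rho, m$u)
    cd <- vs$directions
    coef <- -(1 - 1 / (2 * tau))
    list(
      xx = coef * colSums(cd[, 1] * cd[, 1] * fneq),
      yy = coef * colSums(cd[, 2] * cd[, 2] * fneq),
      zz = coef * colSums(cd[, 3] * cd[, 3] * fneq),
      xy = coef * colSums(cd[, 1] * cd[, 2] * fneq),
      xz = coef * colSums(cd[, 1] * cd[, 3] * fneq),
      yz = coef * colSums(cd[, 2] * cd[, 3] * fneq)
    )
  }
  sig <- stress6(wall_adj)
  sxx <- sig$xx; syy <- sig$yy; szz <- sig$zz
  sxy <- sig$xy; sxz <- sig$xz; syz <- sig$yz

  B <- smooth_solid_indicator(domain)
  d <- dim(B)
  sites <- domain$sites[wall_adj, , drop = FALSE]
  wrap <- function(v, ax) {
    if (domain$periodic[ax]) ((v - 1L) %% d[ax]) + 1L else pmin(pmax(v, 1L), d[ax])
  }
  lin <- function(i, j, k) i + (j - 1L) * d[1] + (k - 1L) * d[1] * d[2]
  gx <- (B[lin(wrap(sites[, 1] + 1L, 1), sites[, 2], sites[, 3])] -
         B[lin(wrap(sites[, 1] - 1L, 1), sites[, 2], sites[, 3])]) / 2
  gy <- (B[lin(sites[, 1], wrap(sites[, 2] + 1L, 2), sites[, 3])] -
         B[lin(sites[, 1], wrap(sites[, 2] - 1L, 2), sites[, 3])]) / 2
  gz <- (B[lin(sites[, 1], sites[, 2], wrap(sites[, 3] + 1L, 3))] -
         B[lin(sites[, 1], sites[, 2], wrap(sites[, 3] - 1L, 3))]) / 2
  gn <- sqrt(gx^2 + gy^2 + gz^2)
  ok <- gn > 1e-8
  n_skip <- sum(!ok)
  nx <- gx[ok] / gn[ok]; ny <- gy[ok] / gn[ok]; nz <- gz[ok] / gn[ok]
  sxx <- sxx[ok]; syy <- syy[ok]; szz <- szz[ok]
  sxy <- sxy[ok]; sxz <- sxz[ok]; syz <- syz[ok]

  if (extrapolate) {
    # Linear extrapolation of the stress tensor from the element site to
    # the bounce-back wall plane half a link away along the normal. The
    # interior sample sits one lattice step along the dominant normal
    # axis, i.e. |n_dom| * dx along the normal, so the extrapolation
    # factor is g = 0.5 / |n_dom|:
    # sigma_wall = (1 + g) sigma(site) - g sigma(interior).
    sk0 <- domain$sites[wall_adj[ok], , drop = FALSE]
    dom_ax <- max.col(cbind(abs(nx), abs(ny), abs(nz)))
    ncomp <- cbind(nx, ny, nz)[cbind(seq_len(nrow(sk0)), dom_ax)]
    step <- matrix(0L, nrow(sk0), 3)
    step[cbind(seq_len(nrow(sk0)), dom_ax)] <- as.integer(sign(ncomp))
    nb_ijk <- sk0 - step
    for (a in 1:3) {
      if (domain$periodic[a]) {
        nb_ijk[, a] <- ((nb_ijk[, a] - 1L) %% domain$shape[a]) + 1L
      } else {
        nb_ijk[, a] <- pmin(pmax(nb_ijk[, a], 1L), domain$shape[a])
      }
    }
    nb <- domain$site_id[nb_ijk]
    has_nb <- nb > 0L
    if (any(has_nb)) {
      g <- 0.5 / pmax(abs(ncomp[has_nb]), 0.5)
      signb <- stress6(nb[has_nb])
      for (comp in c("xx", "yy", "zz", "xy", "xz", "yz")) {
        cur <- switch(comp, xx = sxx, yy = syy, zz = szz,
                      xy = sxy, xz = sxz, yz = syz)
        cur[has_nb] <- (1 + g) * cur[has_nb] - g * signb[[comp]]
        assign(paste0("s", comp), cur)
      }
    }
  }

  tx <- sxx * nx + sxy * ny + sxz * nz
  ty <- sxy * nx + syy * ny + syz * nz
  tz <- sxz * nx + syz * ny + szz * nz
  tn <- tx * nx + ty * ny + tz * nz
  wss_lat <- sqrt((tx - tn * nx)^2 + (ty - tn * ny)^2 + (tz - tn * nz)^2)

  sk <- sites[ok, , drop = FALSE]
  out <- tibble::tibble(
    i = sk[, 1], j = sk[, 2], k = sk[, 3],
    x = domain$origin[1] + (sk[, 1] - 0.5) * domain$dx,
    y = domain$origin[2] + (sk[, 2] - 0.5) * domain$dx,
    z = domain$origin[3] + (sk[, 3] - 0.5) * domain$dx,
    nx = nx, ny = ny, nz = nz,
    wss_pa = wss_lat * units$stress
  )
  attr(out, "skipped") <- n_skip
  out
}

#' Clamp a WSS field to a display range
#'
#' Exports of wall-shear-stress maps conventionally clamp to a fixed range
#' so that healthy/stroke contrasts are comparable; the default range is
#' 0--20 Pa.
#'
#' @param wss A tibble from [wss_field()].
#' @param range Length-2 numeric clamp, Pa.
#' @return The tibble with `wss_pa` clamped.
#' @export
clamp_wss <- function(wss, range = c(0, 20)) {
  wss$wss_pa <- pmin(range[2], pmax(range[1], wss$wss_pa))
  wss
}
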