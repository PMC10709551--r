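# Parametric vessel-network specifications. A network is a set of capsule
# segments (cylinders with hemispherical joins; flat ends where a cap sits)
# plus labelled inlet/outlet caps on axis-aligned planes. These stand in for
# image-derived vasculature: simple enough to voxelise exactly, rich enough
# to reproduce the topology of the circle of Willis.

#' Create a single vessel segment
#'
#' @param from,to Length-3 numeric endpoints in metres.
#' @param radius Radius at `from` in metres.
#' @param radius2 Radius at `to` (defaults to `radius`; a different value
#'   gives a linear taper).
#' @param label Segment label.
#' @param flat_start,flat_end If `TRUE` the segment ends with a flat cut at
#'   that endpoint (used under inlet/outlet caps); otherwise it ends with a
#'   hemispherical join.
#' @return A one-row tibble.
#' @export
vessel_segment <- function(from, to, radius, radius2 = radius, label = "",
                           flat_start = FALSE, flat_end = FALSE) {
  stopifnot(length(from) == 3, length(to) == 3)
  if (all(from == to)) abort_geometry("Segment endpoints must be distinct.")
  if (radius <= 0 || radius2 <= 0) abort_geometry("Segment radii must be positive.")
  tibble::tibble(
    label = label,
    x1 = from[1], y1 = from[2], z1 = from[3],
    x2 = to[1], y2 = to[2], z2 = to[3],
    r1 = radius, r2 = radius2,
    flat1 = flat_start, flat2 = flat_end
  )
}

#' Assemble a vessel network
#'
#' @param segments A tibble of rows from [vessel_segment()].
#' @param caps A tibble with columns `label`, `kind`
#'   (`"inlet"`/`"outlet"`), `x`, `y`, `z` (cap-plane centre, metres),
#'   `axis` (1, 2 or 3), `sign` (+1/-1, the outward plane normal), and
#'   `radius` (metres).
#' @param removable Character vector of segment labels that variants may
#'   remove (e.g. the posterior communicating arteries).
#' @return An object of class `vessel_network`.
#' @export
vessel_network <- function(segments, caps, removable = character()) {
  if (anyDuplicated(caps$label)) abort_geometry("Cap labels must be unique.")
  if (!all(caps$kind %in% c("inlet", "outlet"))) {
    abort_geometry("Cap kind must be 'inlet' or 'outlet'.")
  }
  structure(
    list(segments = segments, caps = caps, removable = removable),
    class = "vessel_network"
  )
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf(
    "<vessel_network> %d segments, %d inlets, %d outlets\n",
    nrow(x$segments), sum(x$caps$kind == "inlet"), sum(x$caps$kind == "outlet")
  ))
  invisible(x)
}

axis_unit <- function(axis, sign = 1) {
  e <- c(0, 0, 0)
  e[axis] <- sign
  e
}

#' Straight-tube fixture
#'
#' A constant-radius tube along one axis with an inlet at the start and an
#' outlet at the end; the basic Poiseuille validation geometry.
#'
#' @param radius Tube radius (m).
#' @param length Tube length (m).
#' @param axis Axis the tube runs along (1, 2 or 3; default 2, the y axis).
#' @return A `vessel_network`.
#' @export
build_tube <- function(radius, length, axis = 2) {
  if (radius <= 0 || length <= 0) abort_geometry("Tube dimensions must be positive.")
  from <- c(0, 0, 0)
  to <- axis_unit(axis) * length
  seg <- vessel_segment(from, to, radius, label = "tube",
                        flat_start = TRUE, flat_end = TRUE)
  caps <- tibble::tibble(
    label = c("in", "out"),
    kind = c("inlet", "outlet"),
    x = c(from[1], to[1]), y = c(from[2], to[2]), z = c(from[3], to[3]),
    axis = axis, sign = c(-1, 1), radius = radius
  )
  vessel_network(seg, caps)
}

#' Symmetric bifurcation fixture
#'
#' A parent tube splitting into two mirror-symmetric daughters. Each
#' daughter runs obliquely at `half_angle` from the parent axis and then
#' turns into an axis-aligned arm so its outlet cap is planar. Used for the
#' flow-split symmetry validation.
#'
#' @param r_parent,r_daughter Radii (m).
#' @param half_angle Angle between each daughter and the parent axis, in
#'   degrees.
#' @param l_parent,l_oblique,l_arm Lengths (m) of the parent, the oblique
#'   daughter portion, and the axis-aligned outlet arm.
#' @return A `vessel_network`, mirror symmetric about the x = 0 plane.
#' @export
build_bifurcation <- function(r_parent = 1.2e-3, r_daughter = 0.9e-3,
                              half_angle = 45, l_parent = 6e-3,
                              l_oblique = 7e-3, l_arm = 4e-3) {
  if (half_angle <= 0 || half_angle >= 90) {
    abort_geometry("`half_angle` must lie strictly between 0 and 90 degrees.")
  }
  th <- half_angle * pi / 180
  junction <- c(0, l_parent, 0)
  elbow_r <- junction + l_oblique * c(sin(th), cos(th), 0)
  # self-intersection guard: the two daughters must separate
  if (2 * elbow_r[1] < 2.5 * r_daughter) {
    abort_geometry(paste0(
      "Daughter branches overlap along their length (separation ",
      format(2 * elbow_r[1]), " m at the elbows); increase `half_angle` ",
      "or `l_oblique`."
    ))
  }
  elbow_l <- elbow_r * c(-1, 1, 1)
  out_r <- elbow_r + c(l_arm, 0, 0)
  out_l <- out_r * c(-1, 1, 1)
  segs <- dplyr::bind_rows(
    vessel_segment(c(0, 0, 0), junction, r_parent, label = "parent",
                   flat_start = TRUE),
    vessel_segment(junction, elbow_r, r_daughter, label = "daughter-R"),
    vessel_segment(junction, elbow_l, r_daughter, label = "daughter-L"),
    vessel_segment(elbow_r, out_r, r_daughter, label = "arm-R", flat_end = TRUE),
    vessel_segment(elbow_l, out_l, r_daughter, label = "arm-L", flat_end = TRUE)
  )
  caps <- tibble::tibble(
    label = c("in", "out-R", "out-L"),
    kind = c("inlet", "outlet", "outlet"),
    x = c(0, out_r[1], out_l[1]),
    y = c(0, out_r[2], out_l[2]),
    z = c(0, out_r[3], out_l[3]),
    axis = c(2, 1, 1), sign = c(-1, 1, -1),
    radius = c(r_parent, r_daughter, r_daughter)
  )
  vessel_network(segs, caps)
}

#' Idealised circle of Willis
#'
#' A planar, parametric circle of Willis with the topology of the cerebral
#' arterial ring: three inlets (basilar artery and the two internal carotid
#' arteries), six outlets (left/right posterior, middle and anterior
#' cerebral arteries), and the communicating segments (left/right posterior
#' communicating arteries, anterior communicating artery, the P1 and A1
#' trunks). The two posterior communicating arteries are flagged removable;
#' the `variant` argument drops one of them, modelling the common anatomical
#' variants in which a PCoA is absent (or, equivalently, a PCoA blocked by
#' stagnant fluid, since the remaining wall closes smoothly).
#'
#' Default radii are literature-typical calibres (metres): ICA 2.0 mm,
#' BA 1.6 mm, MCA 1.4 mm, PCA/ACA/A1/P1 1.2 mm, PCoA/ACoA 0.7 mm. The ring
#' spans roughly 25 x 20 mm in the x-y plane with the carotid inlets
#' entering along z. The layout is mirror symmetric about x = 0.
#'
#' @param variant One of `"FULL"`, `"NO_PCOA_LEFT"`, `"NO_PCOA_RIGHT"`.
#' @param radii Named list overriding any of `ica`, `ba`, `mca`, `pca`,
#'   `aca`, `pcoa`, `acoa` (metres).
#' @param scale Global geometric scale factor.
#' @return A `vessel_network`.
#' @export
#' @examples
#' cow <- build_idealized_cow("FULL")
#' cow$caps[, c("label", "kind")]
build_idealized_cow <- function(variant = c("FULL", "NO_PCOA_LEFT", "NO_PCOA_RIGHT"),
                                radii = list(), scale = 1) {
  variant <- match.arg(variant)
  r <- utils::modifyList(list(
    ica = 2.0e-3, ba = 1.6e-3, mca = 1.4e-3, pca = 1.2e-3,
    aca = 1.2e-3, pcoa = 0.7e-3, acoa = 0.7e-3
  ), radii)
  mm <- 1e-3 * scale
  # junctions (x lateral: left < 0; y posterior -> anterior; z inferior -> 0)
  BB <- c(0, -6, 0) * mm       # basilar bifurcation
  PL <- c(-6, -6, 0) * mm      # left PCA junction
  PR <- c(6, -6, 0) * mm
  CL <- c(-6, 0, 0) * mm       # left carotid terminus
  CR <- c(6, 0, 0) * mm
  AL <- c(-3, 5, 0) * mm       # left ACA junction
  AR <- c(3, 5, 0) * mm
  segs <- dplyr::bind_rows(
    vessel_segment(c(0, -12, 0) * mm, BB, r$ba, label = "BA", flat_start = TRUE),
    vessel_segment(BB, PL, r$pca, label = "P1-L"),
    vessel_segment(BB, PR, r$pca, label = "P1-R"),
    vessel_segment(PL, c(-6, -11, 0) * mm, r$pca, label = "LPCA", flat_end = TRUE),
    vessel_segment(PR, c(6, -11, 0) * mm, r$pca, label = "RPCA", flat_end = TRUE),
    vessel_segment(c(-6, 0, -7) * mm, CL, r$ica, label = "ICA-L", flat_start = TRUE),
    vessel_segment(c(6, 0, -7) * mm, CR, r$ica, label = "ICA-R", flat_start = TRUE),
    vessel_segment(CL, PL, r$pcoa, label = "PCoA-L"),
    vessel_segment(CR, PR, r$pcoa, label = "PCoA-R"),
    vessel_segment(CL, c(-12, 0, 0) * mm, r$mca, label = "LMCA", flat_end = TRUE),
    vessel_segment(CR, c(12, 0, 0) * mm, r$mca, label = "RMCA", flat_end = TRUE),
    vessel_segment(CL, AL, r$aca, label = "A1-L"),
    vessel_segment(CR, AR, r$aca, label = "A1-R"),
    vessel_segment(AL, AR, r$acoa, label = "ACoA"),
    vessel_segment(AL, c(-3, 10, 0) * mm, r$aca, label = "LACA", flat_end = TRUE),
    vessel_segment(AR, c(3, 10, 0) * mm, r$aca, label = "RACA", flat_end = TRUE)
  )
  caps <- tibble::tibble(
    label = c("BA", "LICA", "RICA", "LPCA", "RPCA", "LMCA", "RMCA", "LACA", "RACA"),
    kind = c(rep("inlet", 3), rep("outlet", 6)),
    x = c(0, -6, 6, -6, 6, -12, 12, -3, 3) * mm,
    y = c(-12, 0, 0, -11, -11, 0, 0, 10, 10) * mm,
    z = c(0, -7, -7, 0, 0, 0, 0, 0, 0) * mm,
    axis = c(2, 3, 3, 2, 2, 1, 1, 2, 2),
    sign = c(-1, -1, -1, -1, -1, -1, 1, 1, 1),
    radius = c(r$ba, r$ica, r$ica, r$pca, r$pca, r$mca, r$mca, r$aca, r$aca)
  )
  drop <- switch(variant,
    FULL = character(),
    NO_PCOA_LEFT = "PCoA-L",
    NO_PCOA_RIGHT = "PCoA-R"
  )
  segs <- segs[!segs$label %in% drop, ]
  net <- vessel_network(segs, caps, removable = c("PCoA-L", "PCoA-R"))
  net$variant <- variant
  net
}

#' Mirror a network about the x = 0 plane
#'
#' Reflects all coordinates in x and swaps left/right labels
#' (`L <-> R` prefixes and `-L <-> -R` suffixes). Used to verify
#' construction symmetry.
#'
#' @param network A `vessel_network`.
#' @return The mirrored `vessel_network`.
#' @export
mirror_network <- function(network) {
  swap <- function(s) {
    out <- chartr("LR", "RL", s)
    out
  }
  seg <- network$segments
  seg$x1 <- -seg$x1
  seg$x2 <- -seg$x2
  seg$label <- swap(seg$label)
  caps <- network$caps
  caps$x <- -caps$x
  caps$sign <- ifelse(caps$axis == 1, -caps$sign, caps$sign)
  caps$label <- swap(caps$label)
  vessel_network(seg, caps, removable = swap(network$removable))
}
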