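#' Combine per-direction vessel masks
#'
#' Voxel-wise union of the three velocity-phase masks and the magnitude
#' mask.  Each phase image "sees" only the vessel segments where its
#' velocity component dominates, so a complete vessel volume is obtained by
#' Boolean addition of all four masks.
#'
#' @param phase_masks list of three logical 3D arrays (one per velocity
#'   component).
#' @param magnitude_mask logical 3D array from the magnitude image.
#' @return logical 3D array, the union of the four masks.
#' @export
combine_masks <- function(phase_masks, magnitude_mask) {
  if (length(phase_masks) != 3L) {
    stop_pahemo("`phase_masks` must contain exactly three volumes.")
  }
  dims <- dim(magnitude_mask)
  for (m in phase_masks) {
    if (!identical(dim(m), dims)) {
      stop_pahemo("All masks must share the same array dimensions.")
    }
  }
  out <- magnitude_mask | phase_masks[[1]] | phase_masks[[2]] | phase_masks[[3]]
  storage.mode(out) <- "logical"
  out
}

# 26-connected component labelling of a logical 3D volume via igraph.
# Returns an integer array (0 = background) plus component sizes.
connected_components_3d <- function(volume) {
  d <- dim(volume)
  vox <- which(volume)
  if (!length(vox)) stop_pahemo("Empty volume.")
  id <- integer(prod(d))
  id[vox] <- seq_along(vox)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  ii <- ((vox - 1L) %% nx) + 1L
  jj <- (((vox - 1L) %/% nx) %% ny) + 1L
  kk <- ((vox - 1L) %/% (nx * ny)) + 1L
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[seq_len(13), , drop = FALSE]  # half-neighbourhood
  edges <- list()
  for (o in seq_len(nrow(offsets))) {
    i2 <- ii + offsets[o, 1]; j2 <- jj + offsets[o, 2]; k2 <- kk + offsets[o, 3]
    ok <- i2 >= 1L & i2 <= nx & j2 >= 1L & j2 <= ny & k2 >= 1L & k2 <= nz
    n2 <- (k2[ok] - 1L) * nx * ny + (j2[ok] - 1L) * nx + i2[ok]
    present <- id[n2] > 0L
    edges[[o]] <- cbind(id[vox[ok]][present], id[n2][present])
  }
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(unique(el), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(vox) - igraph::vcount(g)))
  memb <- as.integer(igraph::components(g)$membership)
  lab <- array(0L, dim = d)
  lab[vox] <- memb
  lab
}

#' Largest connected component of a binary volume
#'
#' Retains only the largest 26-connected component; used to clean speckle
#' left by thresholding.  When two components tie in size, the one
#' containing the lexicographically smallest voxel index (array order) is
#' kept.
#'
#' @param volume logical 3D array, nonempty.
#' @return logical 3D array.
#' @export
largest_component <- function(volume) {
  if (!any(volume)) stop_pahemo("Cannot take the largest component of an empty volume.")
  lab <- connected_components_3d(volume)
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie-break: component whose first voxel (array order) comes first
    firsts <- vapply(best, function(b) which(lab == b)[1], numeric(1))
    best <- best[which.min(firsts)]
  }
  lab == best
}

# 2D 8-connected components of a logical matrix; returns an integer matrix.
connected_components_2d <- function(slice) {
  d <- dim(slice)
  vox <- which(slice)
  lab <- matrix(0L, d[1], d[2])
  if (!length(vox)) return(lab)
  id <- integer(prod(d)); id[vox] <- seq_along(vox)
  ii <- ((vox - 1L) %% d[1]) + 1L
  jj <- ((vox - 1L) %/% d[1]) + 1L
  offsets <- cbind(dx = c(1, -1, 0, 1), dy = c(0, 1, 1, 1))
  edges <- list()
  for (o in seq_len(nrow(offsets))) {
    i2 <- ii + offsets[o, 1]; j2 <- jj + offsets[o, 2]
    ok <- i2 >= 1L & i2 <= d[1] & j2 >= 1L & j2 <= d[2]
    n2 <- (j2[ok] - 1L) * d[1] + i2[ok]
    present <- id[n2] > 0L
    edges[[o]] <- cbind(id[vox[ok]][present], id[n2][present])
  }
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(unique(el), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(vox) - igraph::vcount(g)))
  lab[vox] <- as.integer(igraph::components(g)$membership)
  lab
}

#' Partition a vessel mask into MPA, LPA and RPA regions
#'
#' Marches along the axial (z) direction from the inlet and detects the
#' bifurcation as the first cross-section whose lumen is no longer singly
#' connected; everything proximal is labelled MPA.  Distal voxels are
#' assigned to the left or right branch: separated in-slice components by
#' the side (x) of their centroid relative to the MPA centroid, merged
#' cross-sections voxel-by-voxel by side.  A user-supplied bifurcation plane
#' overrides the auto-detection; if no bifurcation is found and a hint is
#' given, the distal part is labelled as a single branch (RPA).
#'
#' @param mask logical 3D array (one connected component).
#' @param spacing voxel spacing (mm).
#' @param origin world position of voxel `[1,1,1]` centre (mm), default 0.
#' @param bifurcation_hint optional [analysis_plane()]; voxels with negative
#'   signed distance are proximal (MPA).
#' @return a `vessel_geometry` (see [generate_bifurcation_geometry()]).
#' @export
label_regions <- function(mask, spacing, origin = c(0, 0, 0),
                          bifurcation_hint = NULL) {
  if (!any(mask)) stop_pahemo("Empty mask.")
  d <- dim(mask)
  ncomp <- vapply(seq_len(d[3]), function(k) {
    s <- mask[, , k]
    if (!any(s)) return(0L)
    max(connected_components_2d(s))
  }, integer(1L))
  occupied <- which(ncomp > 0L)
  labels <- array(0L, dim = d)

  vox <- which(mask)
  ii <- ((vox - 1L) %% d[1]) + 1L
  kk <- ((vox - 1L) %/% (d[1] * d[2])) + 1L
  xw <- origin[1] + (ii - 1) * spacing[1]

  if (!is.null(bifurcation_hint)) {
    jj <- (((vox - 1L) %/% d[1]) %% d[2]) + 1L
    pw <- cbind(xw, origin[2] + (jj - 1) * spacing[2],
                origin[3] + (kk - 1) * spacing[3])
    sd <- sweep(pw, 2, bifurcation_hint$origin) %*% bifurcation_hint$normal
    proximal <- as.numeric(sd) < 0
    bif_k <- NA_integer_
  } else {
    split_k <- occupied[ncomp[occupied] >= 2L]
    if (!length(split_k)) {
      stop_pahemo("No bifurcation found: every cross-section is singly connected; supply `bifurcation_hint`.")
    }
    k_split <- min(split_k)
    # The two branch lumens only separate in-slice some distance beyond the
    # anatomical bifurcation.  A second, earlier signal is the cross-section
    # area: at the bifurcation the single (typically dilated) trunk gives
    # way to two smaller branches, so the slice area drops.  Take the first
    # persistent >10% drop relative to the running proximal median, capped
    # by the connectivity change.
    areas <- vapply(seq_len(d[3]), function(k) sum(mask[, , k]), numeric(1))
    bif_k <- k_split
    ks <- occupied[occupied > min(occupied) + 1L & occupied < k_split]
    for (k in ks) {
      med <- stats::median(areas[min(occupied):(k - 1L)])
      nxt <- if ((k + 1L) %in% occupied) areas[k + 1L] < 0.9 * med else TRUE
      if (areas[k] < 0.9 * med && nxt) {
        bif_k <- k
        break
      }
    }
    proximal <- kk < bif_k
  }
  labels[vox[proximal]] <- 1L
  mpa_cx <- mean(xw[proximal])

  distal <- which(!proximal)
  if (length(distal)) {
    has_bif <- is.null(bifurcation_hint) ||
      any(ncomp[occupied] >= 2L)
    if (!has_bif) {
      labels[vox[distal]] <- 3L
    } else {
      for (k in unique(kk[distal])) {
        sl <- connected_components_2d(mask[, , k])
        rows <- distal[kk[distal] == k]
        cid <- sl[cbind(ii[rows], (((vox[rows] - 1L) %/% d[1]) %% d[2]) + 1L)]
        ncs <- max(sl)
        if (ncs >= 2L) {
          for (cc in seq_len(ncs)) {
            sel <- rows[cid == cc]
            if (!length(sel)) next
            side <- mean(xw[sel]) >= mpa_cx
            labels[vox[sel]] <- if (side) 3L else 2L
          }
        } else {
          labels[vox[rows]] <- ifelse(xw[rows] >= mpa_cx, 3L, 2L)
        }
      }
    }
  }

  inlet_k <- min(occupied)
  inlet_z <- origin[3] + (inlet_k + 0.5) * spacing[3]
  ctr <- c(mean(xw[proximal]),
           origin[2] + (mean((((vox[proximal] - 1L) %/% d[1]) %% d[2]) + 1) - 1) * spacing[2])
  inlet <- analysis_plane(c(ctr[1], ctr[2], inlet_z), c(0, 0, 1))
  outlets <- list()
  for (lbl in c(lpa = 2L, rpa = 3L)) {
    sel <- which(labels == lbl)
    if (!length(sel)) next
    si <- ((sel - 1L) %% d[1]) + 1L
    sj <- (((sel - 1L) %/% d[1]) %% d[2]) + 1L
    sk <- ((sel - 1L) %/% (d[1] * d[2])) + 1L
    kmax <- max(sk)
    far <- sk >= kmax - 1L
    ctr_far <- c(mean(si[far]), mean(sj[far]), mean(sk[far]))
    ctr_all <- c(mean(si), mean(sj), mean(sk))
    nrm <- (ctr_far - ctr_all) * spacing
    orig <- origin + (ctr_far - 1) * spacing
    outlets[[names(which(c(lpa = 2L, rpa = 3L) == lbl))]] <-
      analysis_plane(orig, nrm)
  }

  structure(
    list(mask = mask, labels = labels, spacing = spacing, origin = origin,
         inlet_plane = inlet, outlet_planes = outlets,
         meta = list(bifurcation_slice = bif_k)),
    class = "vessel_geometry"
  )
}

#' Cross-sectional lumen area and equivalent diameter
#'
#' Measures the lumen area cut by a plane as the in-plane sample count times
#' the sample area (the in-plane grid is refined to half the smallest voxel
#' spacing), and the equivalent circular diameter `2*sqrt(area/pi)`.
#'
#' @param geometry a `vessel_geometry`.
#' @param plane an [analysis_plane()].
#' @return a tibble with `area_m2` and `diameter_m`.
#' @export
cross_section_metrics <- function(geometry, plane) {
  grid_sp <- min(geometry$spacing) / 2
  extent <- sum(dim(geometry$mask) * geometry$spacing) / 2
  pg <- plane_grid(plane, extent, grid_sp)
  idx <- world_to_index(pg$points, geometry$origin, geometry$spacing)
  inside <- trilinear(array(as.numeric(geometry$mask), dim(geometry$mask)),
                      idx) >= 0.5
  if (!any(inside)) {
    stop_pahemo("Plane does not intersect the vessel mask.")
  }
  area_m2 <- sum(inside) * pg$area_mm2 * 1e-6
  tibble(area_m2 = area_m2, diameter_m = 2 * sqrt(area_m2 / pi))
}
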