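# Metatarsal isolation: starting from a manual seed (a point inside the
# target bone on one slice, plus the slice index of the metatarsophalangeal
# joint), follow the bone's connected region slice to slice and record its
# center of mass, yielding the bone centerline.

#' Seed annotation for one bone
#'
#' The two manual inputs the pipeline requires: a point inside the target
#' bone on some slice, and the slice index of the metatarsophalangeal joint
#' (the origin of the longitudinal coordinate). All indices are 1-based.
#'
#' @param seed_slice slice index containing the seed point.
#' @param x,y in-slice coordinates (row, column) of a point inside the bone.
#' @param joint_z slice index of the metatarsophalangeal joint.
#' @param stack_id optional identifier carried through to outputs.
#' @return an object of class `seed_annotation`.
#' @export
seed_annotation <- function(seed_slice, x, y, joint_z, stack_id = "bone") {
  check(seed_slice > joint_z,
        "seed_annotation: seed_slice must lie above (beyond) joint_z")
  structure(list(seed_slice = as.integer(seed_slice), x = x, y = y,
                 joint_z = as.integer(joint_z), stack_id = stack_id),
            class = "seed_annotation")
}

#' Label connected regions of a binary slice
#'
#' 8-connected component labeling with per-region area (pixels) and centroid
#' (center of mass of the member pixels). Components are found on the pixel
#' adjacency graph via `igraph`.
#'
#' @param mask_slice logical matrix.
#' @return list with `labels` (integer matrix, 0 = background) and `table`
#'   (data frame: `label`, `area`, `x`, `y`).
#' @export
label_regions <- function(mask_slice) {
  M <- nrow(mask_slice); N <- ncol(mask_slice)
  fg <- which(mask_slice)
  labels <- matrix(0L, M, N)
  if (length(fg) == 0L)
    return(list(labels = labels,
                table = data.frame(label = integer(), area = integer(),
                                   x = numeric(), y = numeric())))
  id <- matrix(0L, M, N)
  id[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% M) + 1L
  cc <- ((fg - 1L) %/% M) + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rn <- r + off[1]; cn <- cc + off[2]
    ok <- rn >= 1L & rn <= M & cn >= 1L & cn <= N
    nb <- integer(length(fg))
    nb[ok] <- id[cbind(rn[ok], cn[ok])]
    sel <- nb > 0L
    if (any(sel)) edges <- c(edges, rbind(id[fg][sel], nb[sel]))
  }
  g <- igraph::make_graph(edges = edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  labels[fg] <- comp
  tab <- data.frame(
    label = sort(unique(comp)),
    area = as.integer(tabulate(comp)),
    x = as.numeric(tapply(r, comp, mean)),
    y = as.numeric(tapply(cc, comp, mean))
  )
  list(labels = labels, table = tab)
}

# choose the successor region: among candidates overlapping the previous
# footprint ("the shadow"), minimal |area difference|; ties broken by larger
# overlap, then by smaller centroid displacement
pick_successor <- function(lab, prev_idx, prev_area, prev_centroid) {
  hit <- lab$labels[prev_idx]
  hit <- hit[hit > 0L]
  if (length(hit) == 0L) return(NULL)
  ov <- table(hit)
  cand <- as.integer(names(ov))
  tab <- lab$table[match(cand, lab$table$label), ]
  dA <- abs(tab$area - prev_area)
  keep <- which(dA == min(dA))
  if (length(keep) > 1L) {
    ovk <- as.integer(ov)[keep]
    keep <- keep[ovk == max(ovk)]
  }
  if (length(keep) > 1L) {
    dd <- (tab$x[keep] - prev_centroid[1])^2 + (tab$y[keep] - prev_centroid[2])^2
    keep <- keep[which.min(dd)]
  }
  tab$label[keep[1]]
}

#' Track one bone across slices and extract its centerline
#'
#' From the seed region, each neighboring slice's successor region is the
#' connected component that overlaps the previous region's pixel footprint
#' (its "shadow") and has the smallest absolute area difference to it.
#' Tracking runs in both directions from the seed slice and is confined to
#' the measurement interval `[joint_z + near, joint_z + far]` (converted
#' from mm to slices via the voxel size). If no overlapping candidate exists
#' in a slice, tracking stops there with a truncation warning.
#'
#' @param mask 3D logical array (bone mask, e.g. from [segment_stack()]).
#' @param seed a [seed_annotation()].
#' @param voxel_size_um isotropic voxel size in micrometers.
#' @param range_mm measurement interval above the joint, mm (near, far).
#' @return object of class `bone_track`: list with `centerline` (data frame
#'   `slice`, `x`, `y`), `mask` (3D logical array containing only the
#'   tracked bone), `areas`, `seed`, `voxel_size_um`, `range_mm`.
#' @export
track_bone <- function(mask, seed, voxel_size_um = 14.599,
                       range_mm = c(0.75, 3.5)) {
  d <- dim(mask)
  check(length(d) == 3L, "track_bone: mask must be 3D")
  vox_mm <- voxel_size_um / 1000
  z_lo <- max(1L, seed$joint_z + as.integer(ceiling(range_mm[1] / vox_mm)))
  z_hi <- min(d[3], seed$joint_z + as.integer(floor(range_mm[2] / vox_mm)))
  check(z_lo <= z_hi, "track_bone: empty tracked range")
  check(seed$seed_slice >= z_lo && seed$seed_slice <= z_hi,
        "track_bone: seed_slice %d outside tracked range [%d, %d]",
        seed$seed_slice, z_lo, z_hi)
  lab0 <- label_regions(mask[, , seed$seed_slice])
  l0 <- lab0$labels[round(seed$x), round(seed$y)]
  check(l0 > 0L, "track_bone: seed point is not inside a foreground region")

  n_sl <- z_hi - z_lo + 1L
  cx <- rep(NA_real_, n_sl); cy <- rep(NA_real_, n_sl)
  areas <- rep(NA_integer_, n_sl)
  out <- array(FALSE, d)

  record <- function(z, lab, l) {
    i <- z - z_lo + 1L
    row <- lab$table[lab$table$label == l, ]
    cx[i] <<- row$x; cy[i] <<- row$y; areas[i] <<- row$area
    sl <- lab$labels == l
    out[, , z] <<- sl
    list(idx = which(sl), area = row$area, centroid = c(row$x, row$y))
  }

  state0 <- record(seed$seed_slice, lab0, l0)
  for (dir in c(1L, -1L)) {
    state <- state0
    z <- seed$seed_slice + dir
    while (z >= z_lo && z <= z_hi) {
      lab <- label_regions(mask[, , z])
      nxt <- pick_successor(lab, state$idx, state$area, state$centroid)
      if (is.null(nxt)) {
        warning(sprintf("track_bone: tracking truncated at slice %d (no overlapping region)", z))
        break
      }
      state <- record(z, lab, nxt)
      z <- z + dir
    }
  }
  got <- !is.na(cx)
  structure(list(
    centerline = data.frame(slice = (z_lo:z_hi)[got], x = cx[got], y = cy[got]),
    mask = out, areas = areas[got], seed = seed,
    voxel_size_um = voxel_size_um, range_mm = range_mm
  ), class = "bone_track")
}

#' @export
print.bone_track <- function(x, ...) {
  cl <- x$centerline
  cat(sprintf("bone_track '%s': %d slices [%d..%d], joint at slice %d\n",
              x$seed$stack_id, nrow(cl), min(cl$slice), max(cl$slice),
              x$seed$joint_z))
  cat(sprintf("  region area %d-%d px, voxel %.3f um\n",
              min(x$areas), max(x$areas), x$voxel_size_um))
  invisible(x)
}
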