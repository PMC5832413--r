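# Group-level inference on searchlight maps: subject-map standardization and
# group t -> z, threshold-free cluster enhancement (TFCE), max-statistic
# Monte-Carlo permutation FWE correction, cluster reporting, voxel overlap.

#' Group statistic map from subject similarity maps
#'
#' Each subject map is standardized (z-scored) within the mask, then a
#' one-sample t-test across subjects is computed per voxel and converted to a
#' z-statistic via the t CDF.
#'
#' @param subject_maps list of `similarity_map`s on the same mask (>= 3
#'   subjects)
#' @return list of class `group_stat_map` with `z` (per mask voxel),
#'   `voxel_index`, `dims`, `affine`, `n_subjects`
#' @export
group_stat <- function(subject_maps) {
  ns <- length(subject_maps)
  if (ns < 3) stop("need at least 3 subjects")
  nv <- length(subject_maps[[1]]$values)
  if (nv < 2) stop("cannot standardize a single-voxel mask")
  M <- vapply(subject_maps, function(s) {
    if (length(s$values) != nv) stop("subject maps differ in mask size")
    v <- s$values
    mu <- mean(v, na.rm = TRUE); sdv <- sd(v, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0)
      stop("zero within-mask variance for subject ", s$subject)
    (v - mu) / sdv
  }, numeric(nv))                      # nv x ns
  mu <- rowMeans(M)
  sdv <- sqrt(pmax(rowSums((M - mu)^2), 0) / (ns - 1))
  tval <- mu / (sdv / sqrt(ns))
  z <- qnorm(pt(tval, df = ns - 1, lower.tail = FALSE, log.p = TRUE),
             lower.tail = FALSE, log.p = TRUE)
  ref <- subject_maps[[1]]
  structure(list(z = z, voxel_index = ref$voxel_index, dims = ref$dims,
                 affine = ref$affine, n_subjects = ns),
            class = "group_stat_map")
}

#' Threshold-free cluster enhancement
#'
#' `TFCE(v) = sum_h e_h(v)^E h^H dh` over thresholds `h = dh, 2dh, ...` up to
#' the map maximum, where `e_h(v)` is the extent of the supra-threshold
#' connected component containing v. One-sided: nonpositive values contribute
#' nothing (an all-nonpositive map yields all zeros). Defaults are the
#' canonical TFCE parameters E = 0.5, H = 2 with 26-connectivity.
#'
#' @param map a `group_stat_map`, `similarity_map`, or numeric `volume`
#' @param E extent exponent (default 0.5)
#' @param H height exponent (default 2)
#' @param dh threshold step; default `max(map) / 100`
#' @param connectivity 6, 18 or 26 (default 26)
#' @return per-voxel TFCE values in the same container layout as the input:
#'   for map objects, a numeric vector over mask voxels; for a `volume`, a
#'   `volume`
#' @export
tfce <- function(map, E = 0.5, H = 2, dh = NULL, connectivity = 26L) {
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  if (inherits(map, "volume")) {
    arr <- as.array(map); msk <- array(TRUE, dim(arr))
    out <- .tfce_on_array(arr, msk, E, H, dh, connectivity)
    return(volume(out, vol_affine(map)))
  }
  vals <- if (inherits(map, "group_stat_map")) map$z else map$values
  arr <- array(0, map$dims)
  msk <- array(FALSE, map$dims)
  msk[map$voxel_index] <- TRUE
  arr[map$voxel_index] <- ifelse(is.na(vals), 0, vals)
  out <- .tfce_on_array(arr, msk, E, H, dh, connectivity)
  out[map$voxel_index]
}

.tfce_on_array <- function(arr, msk, E, H, dh, connectivity) {
  mx <- max(arr[msk], 0)
  if (mx <= 0) return(array(0, dim(arr)))
  if (is.null(dh)) dh <- mx / 100
  .tfce_cpp(as.numeric(arr), dim(arr), as.logical(msk),
            E, H, dh, as.integer(connectivity))
}

#' Max-TFCE permutation null and FWE-corrected p map
#'
#' Implements the study's two-stage Monte-Carlo scheme. Stage 1: for each
#' subject, `n_subject_null` null similarity maps are built by permuting the
#' object labels of the local searchlight RDMs before comparison with the
#' model (implemented equivalently by applying the inverse permutation to the
#' model RDM, which leaves tau-a unchanged). Stage 2: `n_group` null group
#' maps are assembled by sampling one null map per subject with replacement,
#' passing the assembly through [group_stat()] and [tfce()], and recording the
#' maximum TFCE value. The corrected p at voxel v is
#' `(1 + #{null_max >= TFCE_obs(v)}) / (1 + n_group)`, thresholded at `alpha`
#' (FWE).
#'
#' @param subject_patterns list (one per subject) of whole-volume
#'   `pattern_set`s in the neighborhood voxel ordering
#' @param model model `rdm`
#' @param nb `neighborhoods`
#' @param n_subject_null null maps per subject (study value 100)
#' @param n_group group null assemblies (study value 10000)
#' @param seed RNG seed (restored on exit)
#' @param E,H,dh,connectivity TFCE parameters, see [tfce()]
#' @param alpha FWE threshold (default 0.05)
#' @return list of class `permutation_null` with `null` (sorted max-TFCE
#'   values), `p` (corrected p per mask voxel), `obs_tfce`, `significant`
#'   (logical per mask voxel), `group_map`, `seed`
#' @export
permutation_null <- function(subject_patterns, model, nb,
                             n_subject_null = 100L, n_group = 10000L,
                             seed = NULL, E = 0.5, H = 2, dh = NULL,
                             connectivity = 26L, alpha = 0.05) {
  if (n_subject_null < 1) stop("n_subject_null must be >= 1")
  if (n_group < 100) stop("n_group must be >= 100")
  ns <- length(subject_patterns)
  objects <- rownames(subject_patterns[[1]]$data)
  model <- rdm_align(model, objects)
  mm <- unclass(as.matrix(model))
  mv <- mm[lower.tri(mm)]
  nvox <- length(nb$members)
  with_seed(seed, {
    obs_maps <- vector("list", ns)
    null_maps <- vector("list", ns)   # per subject: nvox x n_subject_null
    for (s in seq_len(ns)) {
      vecs <- searchlight_rdm_vectors(subject_patterns[[s]], nb)
      ok <- !is.na(vecs[1, ])
      zmap <- function(tauvec) {
        full <- rep(NA_real_, nvox)
        full[ok] <- atanh(clamp(tau_to_r(tauvec), -1 + 1e-6, 1 - 1e-6))
        full
      }
      obs_maps[[s]] <- similarity_map(
        zmap(.tau_a_many_cpp(mv, vecs[, ok, drop = FALSE])), nb,
        subject = subject_patterns[[s]]$subject,
        context = subject_patterns[[s]]$context)
      nm <- matrix(NA_real_, nvox, n_subject_null)
      for (it in seq_len(n_subject_null)) {
        p <- sample.int(nrow(mm))
        pm <- mm[p, p]
        nm[, it] <- zmap(.tau_a_many_cpp(pm[lower.tri(pm)],
                                         vecs[, ok, drop = FALSE]))
      }
      null_maps[[s]] <- nm
    }
    gmap <- group_stat(obs_maps)
    obs_tfce <- tfce(gmap, E = E, H = H, dh = dh, connectivity = connectivity)
    # fix dh from the observed map so null and observed TFCE share a scale
    dh_used <- dh %||% (max(gmap$z[is.finite(gmap$z)], 0) / 100)
    if (dh_used <= 0) dh_used <- 1e-3
    null_max <- numeric(n_group)
    draw_map <- function(mat, j, proto) {
      proto$values <- mat[, j]
      proto
    }
    proto <- obs_maps[[1]]
    for (g in seq_len(n_group)) {
      pick <- sample.int(n_subject_null, ns, replace = TRUE)
      assembly <- lapply(seq_len(ns), function(s)
        draw_map(null_maps[[s]], pick[s], obs_maps[[s]]))
      gz <- group_stat(assembly)
      tz <- tfce(gz, E = E, H = H, dh = dh_used, connectivity = connectivity)
      null_max[g] <- max(tz, 0)
    }
    null_sorted <- sort(null_max)
    pmap <- (1 + vapply(obs_tfce, function(v)
      sum(null_sorted >= v), numeric(1))) / (1 + n_group)
    structure(list(null = null_sorted, p = pmap, obs_tfce = obs_tfce,
                   significant = pmap < alpha, group_map = gmap,
                   n_subject_null = n_subject_null, n_group = n_group,
                   alpha = alpha, seed = seed),
              class = "permutation_null")
  })
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation null: %d group assemblies, %d significant voxel(s) at FWE alpha = %g\n",
              x$n_group, sum(x$significant), x$alpha))
  invisible(x)
}

#' Cluster report for a thresholded map
#'
#' Labels the connected components of a binary (or thresholded) map and
#' reports, per cluster: extent in voxels, peak statistic with its world-mm
#' coordinates (when a statistic volume is supplied), and the unweighted
#' center of mass in world mm.
#'
#' @param mask logical `volume` (or 3D array) of suprathreshold voxels
#' @param connectivity 6, 18 or 26 (default 26)
#' @param affine 4x4 affine; defaults to the mask's
#' @param stat optional numeric volume/array of the statistic for peak lookup
#' @return `data.frame` of class `cluster_table` with columns `label`,
#'   `extent`, `peak_stat`, `peak_x/y/z`, `com_x/y/z`
#' @export
cluster_report <- function(mask, connectivity = 26L, affine = NULL, stat = NULL) {
  affine <- affine %||% attr(mask, "affine") %||% diag(c(2, 2, 2, 1))
  arr <- as.array(mask)
  lab <- .label_components_cpp(as.logical(arr), dim(arr), as.integer(connectivity))
  nclust <- max(lab)
  cols <- c("label", "extent", "peak_stat", "peak_x", "peak_y", "peak_z",
            "com_x", "com_y", "com_z")
  if (nclust == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, length(cols),
                                dimnames = list(NULL, cols)))
    class(out) <- c("cluster_table", "data.frame")
    return(out)
  }
  rows <- lapply(seq_len(nclust), function(cl) {
    idx <- which(lab == cl, arr.ind = TRUE)
    com <- colMeans(voxel_to_world(idx, affine))
    if (!is.null(stat)) {
      sv <- as.array(stat)[lab == cl]
      pk <- which.max(sv)
      peak_stat <- sv[pk]
      peak_xyz <- voxel_to_world(idx[pk, , drop = FALSE], affine)[1, ]
    } else {
      peak_stat <- NA_real_
      peak_xyz <- c(NA_real_, NA_real_, NA_real_)
    }
    data.frame(label = cl, extent = nrow(idx), peak_stat = peak_stat,
               peak_x = peak_xyz[1], peak_y = peak_xyz[2], peak_z = peak_xyz[3],
               com_x = com[1], com_y = com[2], com_z = com[3])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' Voxel-overlap analysis of thresholded maps
#'
#' Voxelwise logical AND of two or more thresholded binary maps in the same
#' space, with a cluster report of the intersection (extent and center of
#' mass; no peak statistic, since the inputs are binary).
#'
#' @param maps list of logical `volume`s (same dims and affine)
#' @param connectivity 6, 18 or 26
#' @return list with `map` (logical `volume`) and `clusters` (`cluster_table`)
#' @export
overlap <- function(maps, connectivity = 26L) {
  stopifnot(length(maps) >= 2)
  ref_dim <- dim(maps[[1]]); ref_aff <- attr(maps[[1]], "affine")
  for (m in maps) {
    if (!identical(dim(m), ref_dim) ||
        !isTRUE(all.equal(attr(m, "affine"), ref_aff)))
      stop("maps are not in the same space")
  }
  inter <- Reduce(`&`, lapply(maps, as.array))
  v <- volume(inter, ref_aff)
  list(map = v, clusters = cluster_report(v, connectivity, ref_aff))
}
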