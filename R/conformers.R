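# Dihedral-based conformer classification of ligand time series: a minor-
# groove binder exchanging between conformers is characterized by two
# scaffold dihedrals (phi1, phi2); frames are assigned to named conformers
# by a periodic box threshold around each mode centre, the remainder being
# transition structures.

#' Dihedral time series container
#'
#' @param phi1,phi2 dihedral angles, degrees in `(-180, 180]`
#' @param stride_ps optional time stride between frames, ps
#' @return object of class `dihedral_series` (a data.frame)
#' @export
dihedral_series <- function(phi1, phi2, stride_ps = NA_real_) {
  stopifnot(length(phi1) == length(phi2), length(phi1) >= 1)
  if (any(phi1 <= -180 | phi1 > 180 | phi2 <= -180 | phi2 > 180, na.rm = TRUE))
    stop("dihedrals must lie in (-180, 180] degrees")
  structure(data.frame(phi1 = as.numeric(phi1), phi2 = as.numeric(phi2)),
            stride_ps = stride_ps,
            class = c("dihedral_series", "data.frame"))
}

#' Conformer model: named mode centres plus a threshold
#'
#' Each centre `(c1, c2)` also matches its per-coordinate sign images
#' `(+/-c1, +/-c2)`, following the `phi ~ +/-180, +/-90` convention used to
#' describe ligand conformers.  A frame belongs to a mode iff both
#' coordinates are within `threshold` of the (sign-matched) centre under the
#' periodic metric; frames matching no mode are transitions.
#'
#' @param centers data.frame (or list of lists) with `label`, `phi1`, `phi2`
#' @param threshold box half-width, degrees, in (0, 90)
#' @param metric `"box"` (both coordinates within threshold; default) or
#'   `"euclidean"` (periodic Euclidean distance within threshold)
#' @return object of class `conformer_model`
#' @export
conformer_model <- function(centers, threshold = 45,
                            metric = c("box", "euclidean")) {
  metric <- match.arg(metric)
  if (!is.data.frame(centers))
    centers <- do.call(rbind, lapply(centers, function(m)
      data.frame(label = m$label, phi1 = m$phi1, phi2 = m$phi2)))
  if (nrow(centers) > 0 && anyDuplicated(centers$label))
    stop("conformer labels must be unique")
  stopifnot(threshold > 0, threshold < 90)
  structure(list(centers = centers, threshold = threshold, metric = metric),
            class = "conformer_model")
}

#' Paper-style three-conformer model for a minor-groove binder
#'
#' Flat (1): phi1 ~ phi2 ~ 180; out-of-plane aliphatic chain (1a):
#' phi1 ~ phi2 ~ 90; perpendicular cationic head (2): phi1 ~ 180,
#' phi2 ~ 90; threshold 45 degrees.
#'
#' @param threshold degrees
#' @return a [conformer_model()]
#' @export
netropsin_conformer_model <- function(threshold = 45) {
  conformer_model(data.frame(label = c("1", "1a", "2"),
                             phi1 = c(180, 90, 180),
                             phi2 = c(180, 90, 90)),
                  threshold = threshold)
}

#' Periodic angular distance
#'
#' `min(|a - b|, 360 - |a - b|)` in degrees, in `[0, 180]`.
#'
#' @param a,b angles in degrees
#' @return distance in degrees
#' @export
angular_distance <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

ang_dist_deg <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# distance of a frame to one centre under sign symmetry; returns the
# max-coordinate (box) and euclidean distances of the best sign image
frame_mode_distance <- function(p1, p2, c1, c2) {
  d1 <- pmin(ang_dist_deg(p1, c1), ang_dist_deg(p1, -c1))
  d2 <- pmin(ang_dist_deg(p2, c2), ang_dist_deg(p2, -c2))
  list(box = pmax(d1, d2), euc = sqrt(d1^2 + d2^2))
}

#' Classify frames into conformers
#'
#' A frame is assigned to a mode iff its (sign-symmetric, periodic) distance
#' to the mode centre is within the threshold on both coordinates (`"box"`
#' metric) or in the Euclidean sense.  If several modes qualify, the nearest
#' by max-coordinate distance wins; exact ties go to the mode declared
#' first.  Unmatched frames are `"transition"`.
#'
#' @param series a [dihedral_series()] (or anything with `phi1`, `phi2`)
#' @param model a [conformer_model()]
#' @return character vector of labels
#' @export
classify_frames <- function(series, model) {
  stopifnot(inherits(model, "conformer_model"))
  n <- length(series$phi1)
  cen <- model$centers
  if (nrow(cen) == 0) return(rep("transition", n))
  dmat <- matrix(Inf, n, nrow(cen))
  qual <- matrix(FALSE, n, nrow(cen))
  for (m in seq_len(nrow(cen))) {
    d <- frame_mode_distance(series$phi1, series$phi2,
                             cen$phi1[m], cen$phi2[m])
    dmat[, m] <- d$box
    qual[, m] <- if (model$metric == "box") d$box <= model$threshold
                 else d$euc <= model$threshold
  }
  dmat[!qual] <- Inf
  best <- apply(dmat, 1, function(z) if (all(!is.finite(z))) 0L
                                     else which.min(z))
  ifelse(best == 0L, "transition", as.character(cen$label)[pmax(best, 1L)])
}

#' @rdname classify_frames
#' @param phi1,phi2 a single frame, degrees
#' @return `classify_frame()`: one label
#' @export
classify_frame <- function(phi1, phi2, model) {
  classify_frames(data.frame(phi1 = phi1, phi2 = phi2), model)
}

#' Conformer populations of a time series
#'
#' @param series a [dihedral_series()]
#' @param model a [conformer_model()]
#' @return data.frame with `label`, `count`, `fraction` (fractions sum to 1
#'   exactly), transition row last
#' @export
population_table <- function(series, model) {
  lab <- classify_frames(series, model)
  labels <- c(as.character(model$centers$label), "transition")
  counts <- vapply(labels, function(l) sum(lab == l), numeric(1))
  data.frame(label = labels, count = as.integer(counts),
             fraction = counts / length(lab), row.names = NULL)
}

#' Detect conformer modes from the 2D dihedral histogram
#'
#' Builds a periodic 2D histogram of `(phi1, phi2)`, finds local maxima above
#' `prominence` (a fraction of the tallest peak) over a periodic
#' neighbourhood, merges peaks closer than `min_separation`, and returns the
#' surviving centres as a [conformer_model()] sorted by peak mass.
#'
#' @param series a [dihedral_series()] with at least 100 frames
#' @param bin_width histogram bin width, degrees (must divide 360)
#' @param min_separation merge radius, degrees (periodic box distance)
#' @param prominence minimum peak height as a fraction of the tallest peak
#' @param min_contrast required ratio of the tallest peak to the mean
#'   occupancy; a near-uniform histogram has no prominent peak and errors
#' @param threshold threshold for the returned model, degrees
#' @return a [conformer_model()] with labels `"m1"`, `"m2"`, ...
#' @export
detect_modes <- function(series, bin_width = 5, min_separation = 60,
                         prominence = 0.2, min_contrast = 3, threshold = 45) {
  n <- length(series$phi1)
  if (n < 100) stop("mode detection needs at least 100 frames")
  nb <- round(360 / bin_width)
  if (abs(nb * bin_width - 360) > 1e-9) stop("bin width must divide 360")
  bx <- pmin(floor((series$phi1 + 180) / bin_width) + 1, nb)
  by <- pmin(floor((series$phi2 + 180) / bin_width) + 1, nb)
  H <- matrix(0, nb, nb)
  for (i in seq_len(n)) H[bx[i], by[i]] <- H[bx[i], by[i]] + 1
  shift <- function(M, dx, dy) {
    ix <- ((seq_len(nb) - 1 + dx) %% nb) + 1
    iy <- ((seq_len(nb) - 1 + dy) %% nb) + 1
    M[ix, iy]
  }
  # light periodic 3x3 smoothing suppresses single-bin shot noise before
  # peak finding
  Hs <- H * 0
  for (dx in -1:1) for (dy in -1:1) Hs <- Hs + shift(H, dx, dy)
  Hs <- Hs / 9
  # local maxima over the 3x3 periodic neighbourhood of the smoothed field
  ismax <- Hs > 0
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    ismax <- ismax & (Hs >= shift(Hs, dx, dy))
  }
  if (max(Hs) < min_contrast * mean(Hs))
    stop(paste("no prominent histogram peak (max/mean occupancy below the",
               "contrast threshold); lower `min_contrast` if modes are weak"))
  cut <- prominence * max(Hs)
  peaks <- which(ismax & Hs >= cut, arr.ind = TRUE)
  if (nrow(peaks) == 0)
    stop("no histogram peak above the prominence threshold; lower it")
  refine <- function(px, py) {
    num1 <- 0; num2 <- 0; den <- 0
    for (dx in -2:2) for (dy in -2:2) {
      ix <- ((px - 1 + dx) %% nb) + 1
      iy <- ((py - 1 + dy) %% nb) + 1
      wgt <- H[ix, iy]
      num1 <- num1 + wgt * dx; num2 <- num2 + wgt * dy; den <- den + wgt
    }
    c(-180 + (px - 0.5 + num1 / den) * bin_width,
      -180 + (py - 0.5 + num2 / den) * bin_width)
  }
  ref <- t(apply(peaks, 1, function(z) refine(z[1], z[2])))
  centers <- data.frame(phi1 = wrap_deg(ref[, 1]), phi2 = wrap_deg(ref[, 2]),
                        mass = Hs[peaks])
  centers <- centers[order(-centers$mass), ]
  keep <- rep(TRUE, nrow(centers))
  for (i in seq_len(nrow(centers))) {
    if (!keep[i]) next
    if (i < nrow(centers)) for (j in (i + 1):nrow(centers)) {
      if (!keep[j]) next
      d1 <- ang_dist_deg(centers$phi1[i], centers$phi1[j])
      d2 <- ang_dist_deg(centers$phi2[i], centers$phi2[j])
      if (max(d1, d2) < min_separation) keep[j] <- FALSE
    }
  }
  centers <- centers[keep, , drop = FALSE]
  conformer_model(data.frame(label = paste0("m", seq_len(nrow(centers))),
                             phi1 = centers$phi1, phi2 = centers$phi2),
                  threshold = threshold)
}
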