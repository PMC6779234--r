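#' @useDynLib zteac, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# tissue codes shared by the segmentation pipeline
ZTE_AIR_EXTERNAL <- 0L
ZTE_SOFT <- 1L
ZTE_BONE <- 2L
ZTE_AIR_INTERNAL <- 3L

# Otsu threshold on a numeric vector (128 bins over the value range)
otsu_threshold <- function(x, n_bins = 128L) {
  rng <- range(x)
  if (diff(rng) <= 0) stop("cannot threshold a constant volume")
  h <- graphics::hist(x, breaks = seq(rng[1], rng[2], length.out = n_bins + 1),
                      plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# histogram mode over 128 bins, refined as the mean of the values falling
# in the fullest bin (exact when that bin holds a single repeated value)
histogram_mode <- function(x, n_bins = 128L) {
  rng <- range(x)
  if (diff(rng) <= 0) return(x[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  k <- which.max(h$counts)
  sel <- x >= breaks[k] & x <= breaks[k + 1]
  mean(x[sel])
}

#' Normalize a ZTE volume to soft tissue = 1
#'
#' The head mask is the largest 6-connected component of the
#' morphologically closed above-Otsu-threshold mask (closing first bridges
#' the low-intensity core of dense bone, so scalp, skull and brain form a
#' single component); the normalizer is the histogram mode (128 bins) of
#' the in-mask intensities, which rediscovers the soft-tissue level
#' without assuming an absolute scale. Output values are the normalized
#' ZTE intensity IZTE: soft tissue maps to ~1.
#'
#' @param zte a `zteac_volume` of raw ZTE intensities (>= 0).
#' @param close_radius radius (voxels) of the morphological closing applied
#'   to the head mask; bridges the low-intensity core of dense bone.
#' @return list of class `normalized_zte`: `volume` (normalized values),
#'   `head_mask` (logical array), `soft_tissue_mode` (raw normalizer).
#' @export
normalize_zte <- function(zte, close_radius = 2L) {
  stopifnot_volume(zte)
  x <- zte$data
  if (any(x < 0)) stop("ZTE intensities must be >= 0")
  if (all(x == 0)) stop("cannot normalize an all-zero volume")
  mask <- head_mask(x, close_radius)
  mode_raw <- histogram_mode(as.numeric(x[mask]))
  if (mode_raw <= 0) stop("degenerate soft-tissue mode")
  structure(list(volume = volume(x / mode_raw, zte$spacing, "zte"),
                 head_mask = mask, soft_tissue_mode = mode_raw),
            class = "normalized_zte")
}

#' Classify normalized ZTE into air / soft tissue / bone
#'
#' Inside the head mask, normalized intensities in `bone_band` (closed
#' interval) are bone, values above it soft tissue, values below it air
#' (provisionally interior; [mask_sinuses()] resolves interior vs exterior).
#' Outside the mask everything is exterior air. The bone class is then
#' morphologically opened (6-connected, `open_radius`) to remove speckle;
#' voxels removed from bone revert to soft tissue.
#'
#' @param nz a `normalized_zte`.
#' @param bone_band numeric `c(low, high)`, `0 <= low < high`.
#' @param open_radius opening radius in voxels (0 disables).
#' @return list of class `tissue_labels` with `volume` (integer codes:
#'   0 exterior air, 1 soft, 2 bone, 3 interior air) and `head_mask`.
#' @export
classify_tissues <- function(nz, bone_band = c(0.1, 0.85), open_radius = 1L) {
  if (!inherits(nz, "normalized_zte")) stop("nz must come from normalize_zte()")
  if (length(bone_band) != 2L || bone_band[1] < 0 ||
      bone_band[1] >= bone_band[2])
    stop("bone_band must satisfy 0 <= low < high")
  x <- nz$volume$data
  d <- dim(x)
  lab <- array(ZTE_AIR_EXTERNAL, d)
  inm <- nz$head_mask
  lab[inm & x < bone_band[1]] <- ZTE_AIR_INTERNAL
  lab[inm & x >= bone_band[1] & x <= bone_band[2]] <- ZTE_BONE
  lab[inm & x > bone_band[2]] <- ZTE_SOFT
  if (open_radius > 0) {
    bone <- array(lab == ZTE_BONE, d)
    opened <- array(.morph3d(bone, d, as.integer(open_radius), "open"), d)
    lab[bone & !opened] <- ZTE_SOFT
  }
  structure(list(volume = volume(lab, nz$volume$spacing, "label"),
                 head_mask = inm),
            class = "tissue_labels")
}

#' Detect and mask interior air (paranasal-sinus analogue)
#'
#' Air-labelled components that are not 6-connected to the image border are
#' interior air (sinus/mastoid pockets); components touching the border are
#' exterior. Bone components that are completely enclosed by interior air
#' and smaller than `max_enclosed_mm3` are relabelled as interior air, to
#' avoid misclassifying speckle inside sinuses as bone.
#'
#' @param labels a `tissue_labels`.
#' @param max_enclosed_mm3 volume bound (mm^3) for the enclosed-bone rule.
#' @return a `tissue_labels` with interior/exterior air resolved.
#' @export
mask_sinuses <- function(labels, max_enclosed_mm3 = 1000) {
  if (!inherits(labels, "tissue_labels")) stop("labels must be tissue_labels")
  lab <- labels$volume$data
  d <- dim(lab)
  air <- array(lab == ZTE_AIR_EXTERNAL | lab == ZTE_AIR_INTERNAL, d)
  comp <- .label3d(air, d)
  border_ids <- unique(c(comp[1, , ], comp[d[1], , ], comp[, 1, ],
                         comp[, d[2], ], comp[, , 1], comp[, , d[3]]))
  border_ids <- border_ids[border_ids > 0]
  lab[air] <- ifelse(comp[air] %in% border_ids, ZTE_AIR_EXTERNAL,
                     ZTE_AIR_INTERNAL)
  # bone blobs strictly enclosed by interior air
  voxvol <- prod(labels$volume$spacing)
  bone <- array(lab == ZTE_BONE, d)
  if (any(bone)) {
    bcomp <- .label3d(bone, d)
    nb <- max(bcomp)
    if (nb > 0) {
      dil <- array(.morph3d(bone, d, 1L, "dilate"), d)
      shell <- dil & !bone
      for (b in seq_len(nb)) {
        bm <- bcomp == b
        n_vox <- sum(bm)
        if (n_vox * voxvol >= max_enclosed_mm3) next
        sm <- array(.morph3d(array(bm, d), d, 1L, "dilate"), d) & !bm
        if (all(lab[sm] == ZTE_AIR_INTERNAL))
          lab[bm] <- ZTE_AIR_INTERNAL
      }
    }
  }
  structure(list(volume = volume(lab, labels$volume$spacing, "label"),
                 head_mask = labels$head_mask),
            class = "tissue_labels")
}

#' Assign Hounsfield units from tissue classes
#'
#' Air (exterior and interior) maps to -1000 HU, soft tissue to
#' `soft_tissue_hu`, and bone to the continuous density model
#' `42 + 2400 (1 - IZTE)` HU, where IZTE is the normalized ZTE intensity
#' (negative values clipped to 0 before the formula, result clipped below
#' at 42 HU so IZTE > 1 cannot undercut soft tissue).
#'
#' @param labels a `tissue_labels`.
#' @param nz the `normalized_zte` the labels were derived from.
#' @param soft_tissue_hu HU of soft tissue (default 42, continuous with the
#'   bone model at IZTE = 1).
#' @return a `zteac_volume` of Hounsfield units.
#' @export
assign_hu <- function(labels, nz, soft_tissue_hu = 42) {
  if (!inherits(labels, "tissue_labels")) stop("labels must be tissue_labels")
  if (!inherits(nz, "normalized_zte")) stop("nz must come from normalize_zte()")
  lab <- labels$volume$data
  iz <- nz$volume$data
  if (!identical(dim(lab), dim(iz)))
    stop("labels and normalized ZTE have different shapes")
  hu <- array(-1000, dim(lab))
  hu[lab == ZTE_SOFT] <- soft_tissue_hu
  b <- lab == ZTE_BONE
  hu[b] <- pmax(42 + 2400 * (1 - pmax(iz[b], 0)), 42)
  volume(hu, labels$volume$spacing, "hu")
}

#' Segmentation-based pseudo-CT from a ZTE volume
#'
#' Runs the full pipeline: intensity normalization, air/soft/bone
#' classification, interior-air (sinus) masking and HU assignment with the
#' continuous bone-density model.
#'
#' @inheritParams classify_tissues
#' @inheritParams mask_sinuses
#' @inheritParams assign_hu
#' @param zte raw ZTE `zteac_volume`.
#' @return a pseudo-CT `zteac_volume` in HU.
#' @export
zte_pseudoct <- function(zte, bone_band = c(0.1, 0.85), open_radius = 1L,
                         max_enclosed_mm3 = 1000, soft_tissue_hu = 42) {
  nz <- normalize_zte(zte)
  lab <- classify_tissues(nz, bone_band = bone_band, open_radius = open_radius)
  lab <- mask_sinuses(lab, max_enclosed_mm3 = max_enclosed_mm3)
  assign_hu(lab, nz, soft_tissue_hu = soft_tissue_hu)
}
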