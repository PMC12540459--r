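# NIfTI I/O, nnU-Net-style preprocessing to a fixed 1 mm / fixed-shape grid,
# and a synthetic multimodal FCD-like phantom generator so every stage of the
# pipeline can be exercised without patient data.

#' Read a NIfTI file as a volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param reorient reorient to canonical (RAS) axes on load.
#' @return a [volume()] with attribute `affine` (4x4 xform matrix).
#' @export
read_nifti_volume <- function(path, reorient = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    stop("malformed NIfTI file: ", path, " (", conditionMessage(e), ")"))
  if (reorient) RNifti::orientation(img) <- "RAS"
  vals <- as.array(img)
  vals <- array(as.numeric(vals), dim(vals))  # drop RNifti attributes
  if (length(dim(vals)) == 4L && dim(vals)[4] == 1L) vals <- array(vals, dim(vals)[1:3])
  sp <- RNifti::pixdim(img)[1:3]
  v <- volume(vals, sp)
  attr(v, "affine") <- RNifti::xform(img)
  v
}

#' Write a volume to NIfTI
#'
#' Masks (integer 0/1 content) are written as unsigned 8-bit, images as
#' 32-bit float; grid, spacing and (optional) affine round-trip losslessly.
#'
#' @param vol a [volume()] (or 3D array).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param affine optional 4x4 xform; defaults to a diagonal scaling by the
#'   voxel spacing.
#' @return invisibly, the path.
#' @export
write_nifti_volume <- function(vol, path, affine = NULL) {
  vol <- as_volume(vol)
  is_mask <- all(vol$values %in% c(0, 1))
  vals <- vol$values
  if (is.null(affine)) affine <- diag(c(vol$spacing, 1))  # RAS-positive
  img <- RNifti::asNifti(vals, reference = list(pixdim = c(1, vol$spacing, 0, 0, 0, 0)),
                         datatype = if (is_mask) "uint8" else "float")
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Preprocessing configuration
#'
#' @param target_spacing isotropic target spacing in mm (default 1).
#' @param target_shape fixed output grid (must be divisible by 16).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(target_spacing = c(1, 1, 1),
                              target_shape = c(128L, 128L, 128L)) {
  target_spacing <- as.numeric(target_spacing)
  target_shape <- as.integer(target_shape)
  if (any(target_spacing <= 0)) stop("spacing must be positive")
  if (any(target_shape %% 16L != 0L)) stop("target shape must be divisible by 16")
  structure(list(target_spacing = target_spacing, target_shape = target_shape),
            class = "preprocess_config")
}

# Resample one axis to given 0-based source positions.
interp_axis_pos <- function(x, pos, axis, method = "linear") {
  n <- dim(x)[axis]
  pos <- pmin(pmax(pos, 0), n - 1)
  if (method == "nearest") {
    i <- as.integer(round(pos)) + 1L
    return(switch(axis, x[i, , , drop = FALSE], x[, i, , drop = FALSE],
                  x[, , i, drop = FALSE]))
  }
  i0 <- pmin(floor(pos), n - 2); w <- pos - i0
  if (n == 1L) { i0 <- rep(0, length(pos)); w <- rep(0, length(pos)) }
  i0 <- as.integer(i0) + 1L; i1 <- pmin(i0 + 1L, n)
  a <- switch(axis, x[i0, , , drop = FALSE], x[, i0, , drop = FALSE], x[, , i0, drop = FALSE])
  b <- switch(axis, x[i1, , , drop = FALSE], x[, i1, , drop = FALSE], x[, , i1, drop = FALSE])
  m <- length(pos); d <- dim(x)
  wr <- switch(axis, array(w, c(m, d[2], d[3])),
               aperm(array(w, c(m, d[1], d[3])), c(2, 1, 3)),
               aperm(array(w, c(m, d[1], d[2])), c(2, 3, 1)))
  (1 - wr) * a + wr * b
}

# Voxel-center-aligned resampling of a 3D array between spacings.
resample_array <- function(v, old_spacing, new_spacing, method = "linear",
                           new_dim = NULL) {
  d <- dim(v)
  if (is.null(new_dim)) new_dim <- pmax(1L, as.integer(round(d * old_spacing / new_spacing)))
  for (a in 1:3) {
    scale <- old_spacing[a] / new_spacing[a]
    pos <- ((seq_len(new_dim[a]) - 0.5) / scale) - 0.5
    v <- interp_axis_pos(v, pos, a, method)
  }
  v
}

#' Preprocess a multimodal case to a model-ready tensor
#'
#' Chain: crop to the joint nonzero bounding box of all modalities, resample
#' to the target spacing (trilinear for images, nearest-neighbour for the
#' mask), z-score each modality over its nonzero voxels, and center pad/crop
#' to the fixed target shape. The returned inverse record maps predictions on
#' the network grid back to the native grid.
#'
#' @param case a case list with `volumes` (named list of [volume()], `t1`
#'   first) and optionally `mask` (binary volume).
#' @param cfg a [preprocess_config()].
#' @return list with `tensor` (n_modalities x target shape), `mask` (binary
#'   array on the target grid or NULL), `modalities`, and `inverse`.
#' @export
preprocess_case <- function(case, cfg = preprocess_config()) {
  mods <- case$volumes
  if (is.null(mods$t1)) stop("a t1 volume is required")
  ord <- intersect(c("t1", "flair", "pet"), names(mods))
  mods <- mods[ord]
  d <- dim(mods[[1]]$values)
  for (m in mods) if (!all(dim(m$values) == d)) stop("modality grids differ")
  nz <- Reduce(`|`, lapply(mods, function(m) m$values != 0))
  if (!any(nz)) stop("empty image: no nonzero voxels")
  rng <- lapply(1:3, function(a) {
    pr <- which(apply(nz, a, any))
    c(min(pr), max(pr))
  })
  crop <- function(x) x[rng[[1]][1]:rng[[1]][2], rng[[2]][1]:rng[[2]][2],
                        rng[[3]][1]:rng[[3]][2], drop = FALSE]
  spacing <- mods[[1]]$spacing
  arrs <- lapply(mods, function(m) crop(m$values))
  rs <- lapply(arrs, function(a) resample_array(a, spacing, cfg$target_spacing))
  zs <- lapply(rs, function(a) {
    fg <- a != 0
    if (!any(fg)) return(a)
    a[fg] <- (a[fg] - mean(a[fg])) / max(stats::sd(a[fg]), 1e-8)
    a[!fg] <- 0  # background stays identically zero after normalization
    a
  })
  pc <- lapply(zs, function(a) pad_crop_center(a, cfg$target_shape))
  tensor <- array(0, c(length(pc), cfg$target_shape))
  for (i in seq_along(pc)) tensor[i, , , ] <- pc[[i]]$values
  inverse <- list(native_shape = d, crop_start = vapply(rng, `[`, numeric(1), 1),
                  cropped_shape = dim(arrs[[1]]), resampled_shape = dim(rs[[1]]),
                  spacing = spacing, target_spacing = cfg$target_spacing,
                  pad_offset = pc[[1]]$offset, target_shape = cfg$target_shape)
  mask <- NULL
  if (!is.null(case$mask)) {
    mk <- crop(as_mask_array(case$mask))
    mk <- resample_array(mk, spacing, cfg$target_spacing, method = "nearest")
    mask <- pad_crop_center(mk, cfg$target_shape)$values
    storage.mode(mask) <- "integer"
  }
  list(tensor = tensor, mask = mask, modalities = names(mods), inverse = inverse)
}

#' Map a prediction on the network grid back to the native grid
#'
#' Inverts the pad/crop, resampling (nearest-neighbour) and bounding-box crop
#' recorded by [preprocess_case()].
#'
#' @param mask binary array on the preprocessing target grid.
#' @param inverse the `inverse` record from [preprocess_case()].
#' @return binary array on the native grid.
#' @export
postprocess_to_native <- function(mask, inverse) {
  off <- inverse$pad_offset
  rs_shape <- inverse$resampled_shape
  un <- array(0L, rs_shape)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    if (off[a] >= 0) { src[[a]] <- (off[a] + 1L):(off[a] + min(rs_shape[a], inverse$target_shape[a]))
                       dst[[a]] <- seq_along(src[[a]]) }
    else { src[[a]] <- 1:inverse$target_shape[a]; dst[[a]] <- (-off[a] + 1L):(-off[a] + inverse$target_shape[a]) }
  }
  un[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  cr <- resample_array(un, inverse$target_spacing, inverse$spacing,
                       method = "nearest", new_dim = inverse$cropped_shape)
  out <- array(0L, inverse$native_shape)
  st <- inverse$crop_start
  en <- st + inverse$cropped_shape - 1L
  out[st[1]:en[1], st[2]:en[2], st[3]:en[3]] <- as.integer(cr > 0.5)
  out
}

#' Parameters of the synthetic multimodal phantom
#'
#' The generator emulates co-registered T1/FLAIR/PET-like volumes: an
#' ellipsoidal head containing a smooth two-compartment tissue field, plus
#' small ellipsoidal lesions with Gaussian-blurred edges and per-modality
#' contrast (T1 slightly hypointense, FLAIR-analog hyperintense, PET-analog
#' hypometabolic), with additive Gaussian noise. The ground-truth mask is the
#' pre-blur lesion support. Output is fully determined by `seed`.
#'
#' @param shape grid shape (default 64^3 for desk-scale work; use 128^3 to
#'   match the production grid).
#' @param n_lesions number of lesions.
#' @param semi_axes_range range (voxels) of lesion ellipsoid semi-axes.
#' @param edge_blur_sigma lesion edge blur in voxels.
#' @param contrasts named per-modality additive lesion contrast.
#' @param tissue_levels named list of per-modality two-compartment tissue
#'   intensities (dark, bright); defaults emulate strong gray/white contrast
#'   on T1, weak tissue contrast on FLAIR, intermediate on PET.
#' @param background_smoothness correlation length (voxels) of the tissue field.
#' @param noise_sd additive Gaussian noise sd.
#' @param modalities modalities to synthesize (subset of t1/flair/pet).
#' @param seed RNG seed.
#' @return a `synthetic_params` list.
#' @export
synthetic_params <- function(shape = c(64L, 64L, 64L), n_lesions = 1L,
                             semi_axes_range = c(3, 6), edge_blur_sigma = 1,
                             contrasts = c(t1 = -0.15, flair = 0.35, pet = -0.3),
                             tissue_levels = list(t1 = c(0.45, 0.80),
                                                  flair = c(0.55, 0.65),
                                                  pet = c(0.50, 0.70)),
                             background_smoothness = 4, noise_sd = 0.05,
                             modalities = c("t1", "flair", "pet"), seed = 1L) {
  if (is.null(names(contrasts))) stop("contrasts must be named")
  if (!"t1" %in% modalities) stop("t1 is required")
  structure(list(shape = as.integer(shape), n_lesions = as.integer(n_lesions),
                 semi_axes_range = semi_axes_range,
                 edge_blur_sigma = edge_blur_sigma, contrasts = contrasts,
                 tissue_levels = tissue_levels,
                 background_smoothness = background_smoothness,
                 noise_sd = noise_sd, modalities = modalities,
                 seed = as.integer(seed)),
            class = "synthetic_params")
}

smooth_field <- function(v, sigma) {
  passes <- max(1L, round(sigma^2))  # each binomial pass adds unit variance
  for (i in seq_len(passes)) v <- gs3_arr(v)
  v
}

ellipsoid_mask <- function(shape, center, semi) {
  d1 <- ((seq_len(shape[1]) - center[1]) / semi[1])^2
  d2 <- ((seq_len(shape[2]) - center[2]) / semi[2])^2
  d3 <- ((seq_len(shape[3]) - center[3]) / semi[3])^2
  outer(outer(d1, d2, `+`), d3, `+`) <= 1
}

#' Generate one synthetic multimodal case
#'
#' @param params a [synthetic_params()].
#' @param case_id identifier stored in the case.
#' @return a case list: `case_id`, `volumes` (named [volume()] list),
#'   `mask` (binary volume: the pre-blur lesion support), `params`.
#' @export
generate_synthetic_case <- function(params = synthetic_params(),
                                    case_id = "synthetic_001") {
  set.seed(params$seed)
  sh <- params$shape
  head <- ellipsoid_mask(sh, (sh + 1) / 2, 0.45 * sh)
  tissue <- smooth_field(array(stats::rnorm(prod(sh)), sh),
                         params$background_smoothness)
  thr <- stats::median(tissue[head])
  bright <- array(FALSE, sh)
  bright[head] <- tissue[head] > thr
  # place lesions fully inside the head
  gt <- array(FALSE, sh)
  margin <- max(params$semi_axes_range) + 2
  for (l in seq_len(params$n_lesions)) {
    ok <- FALSE
    for (try in 1:200) {
      ctr <- runif(3, margin, sh - margin)
      if (!head[round(ctr[1]), round(ctr[2]), round(ctr[3])]) next
      semi <- runif(3, params$semi_axes_range[1], params$semi_axes_range[2])
      les <- ellipsoid_mask(sh, ctr, semi)
      if (all(head[les])) { gt <- gt | les; ok <- TRUE; break }
    }
    if (!ok) stop("could not place lesion inside the head analog")
  }
  les_blur <- smooth_field(array(as.numeric(gt), sh), params$edge_blur_sigma)
  vols <- list()
  for (m in params$modalities) {
    lv <- params$tissue_levels[[m]]
    base <- array(0, sh)
    base[head] <- ifelse(bright[head], lv[2], lv[1])
    v <- base + params$contrasts[[m]] * les_blur
    noise <- array(stats::rnorm(prod(sh), sd = params$noise_sd), sh)
    v[head] <- v[head] + noise[head]
    v[!head] <- 0
    vols[[m]] <- volume(v)
  }
  mask <- array(0L, sh); mask[gt] <- 1L
  list(case_id = case_id, volumes = vols, mask = volume(mask), params = params)
}

#' Deterministic k-fold cross-validation split
#'
#' @param case_ids character vector of case identifiers.
#' @param k number of folds (default 5).
#' @param seed RNG seed; the same seed always yields the same folds.
#' @return integer vector of fold assignments (1..k) named by case id; fold
#'   sizes differ by at most 1.
#' @export
make_cv_folds <- function(case_ids, k = 5L, seed = 1L) {
  n <- length(case_ids)
  if (k > n) stop("k must not exceed the number of cases")
  set.seed(seed)
  ord <- sample(n)
  folds <- integer(n)
  folds[ord] <- rep(seq_len(k), length.out = n)
  stats::setNames(folds, case_ids)
}

#' Write a case to a dataset directory
#'
#' Layout: `<dir>/<case_id>/<case_id>_<modality>.nii.gz` plus
#' `<case_id>_mask.nii.gz`.
#'
#' @param case a case list (see [generate_synthetic_case()]).
#' @param dir dataset root directory.
#' @return invisibly, the case directory.
#' @export
write_case <- function(case, dir) {
  cd <- file.path(dir, case$case_id)
  dir.create(cd, recursive = TRUE, showWarnings = FALSE)
  for (m in names(case$volumes))
    write_nifti_volume(case$volumes[[m]],
                       file.path(cd, sprintf("%s_%s.nii.gz", case$case_id, m)))
  if (!is.null(case$mask))
    write_nifti_volume(case$mask,
                       file.path(cd, sprintf("%s_mask.nii.gz", case$case_id)))
  invisible(cd)
}

#' Read a case from a dataset directory
#'
#' @param dir dataset root directory.
#' @param case_id case identifier (a subdirectory of `dir`).
#' @param with_mask read the lesion mask if present.
#' @return a case list.
#' @export
read_case <- function(dir, case_id, with_mask = TRUE) {
  cd <- file.path(dir, case_id)
  vols <- list()
  for (m in c("t1", "flair", "pet")) {
    f <- file.path(cd, sprintf("%s_%s.nii.gz", case_id, m))
    if (file.exists(f)) vols[[m]] <- read_nifti_volume(f)
  }
  if (is.null(vols$t1)) stop("case ", case_id, " has no t1 volume")
  mask <- NULL
  mf <- file.path(cd, sprintf("%s_mask.nii.gz", case_id))
  if (with_mask && file.exists(mf)) {
    mv <- read_nifti_volume(mf)
    mv$values <- array(as.integer(mv$values > 0.5), dim(mv$values))
    mask <- mv
  }
  list(case_id = case_id, volumes = vols, mask = mask)
}

#' Write / read a dataset manifest
#'
#' The manifest (`manifest.json` at the dataset root) lists the case ids and
#' the modalities present.
#'
#' @param dir dataset root.
#' @param case_ids case identifiers.
#' @param modalities modality names.
#' @param extra optional named list stored verbatim.
#' @return the manifest path (write) or the parsed manifest list (read).
#' @export
write_manifest <- function(dir, case_ids, modalities = c("t1", "flair", "pet"),
                           extra = NULL) {
  m <- list(cases = as.list(case_ids), modalities = as.list(modalities))
  if (!is.null(extra)) m <- c(m, extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' @rdname write_manifest
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", dir)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
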