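#' Planted network
#'
#' A synthetic stand-in for one canonical resting-state network: a set of
#' member voxels sharing a latent time-course of a given amplitude. Networks
#' handed to [make_normative_cohort()] must be pairwise disjoint.
#'
#' @param name network label.
#' @param spatial_map a [binary_mask()] of member voxels (>= 2 voxels).
#' @param timecourse_sd standard deviation of the shared latent signal.
#' @return object of class `planted_network`.
#' @export
planted_network <- function(name, spatial_map, timecourse_sd = 1) {
  stopifnot(inherits(spatial_map, "binary_mask"))
  if (mask_count(spatial_map) < 2L)
    stop("a planted network needs at least 2 member voxels")
  if (!is.numeric(timecourse_sd) || timecourse_sd <= 0)
    stop("`timecourse_sd` must be positive")
  structure(list(name = as.character(name), spatial_map = spatial_map,
                 timecourse_sd = timecourse_sd),
            class = "planted_network")
}

#' Tissue model for the synthetic generator
#'
#' Encodes the grey/white-matter asymmetry of BOLD: white-matter member
#' voxels carry the network's latent signal at a fraction `wm_signal_scale`
#' of its grey-matter amplitude (physiological WM BOLD runs at roughly a
#' quarter to a half of GM amplitude), on top of tissue-specific Gaussian
#' noise. `global_signal_sd` adds a weak brain-wide shared component to every
#' in-brain voxel, emulating the non-specific global/physiological signal
#' that gives real resting-state data its widespread low-level positive
#' correlations; set it to 0 for a fully network-specific model.
#'
#' @param gm_mask,wm_mask disjoint [binary_mask()] compartments; their union
#'   is the brain mask.
#' @param gm_noise_sd,wm_noise_sd positive noise standard deviations.
#' @param wm_signal_scale latent amplitude scale in WM, in `[0, 1]`.
#' @param global_signal_sd standard deviation of the brain-wide shared
#'   signal (0 disables it).
#' @return object of class `tissue_model`.
#' @export
tissue_model <- function(gm_mask, wm_mask, gm_noise_sd = 1, wm_noise_sd = 1,
                         wm_signal_scale = 0.35, global_signal_sd = 0) {
  stopifnot(inherits(gm_mask, "binary_mask"), inherits(wm_mask, "binary_mask"))
  stop_if_grid_mismatch(gm_mask$grid, wm_mask$grid, "GM and WM masks")
  if (any(gm_mask$values * wm_mask$values != 0))
    stop("GM and WM masks must be disjoint")
  if (gm_noise_sd <= 0 || wm_noise_sd <= 0)
    stop("noise standard deviations must be positive")
  if (wm_signal_scale < 0 || wm_signal_scale > 1)
    stop("`wm_signal_scale` must lie in [0, 1]")
  if (global_signal_sd < 0) stop("`global_signal_sd` must be >= 0")
  structure(list(gm_mask = gm_mask, wm_mask = wm_mask,
                 gm_noise_sd = gm_noise_sd, wm_noise_sd = wm_noise_sd,
                 wm_signal_scale = wm_signal_scale,
                 global_signal_sd = global_signal_sd),
            class = "tissue_model")
}

#' Brain mask of a tissue model
#' @param tissue a [tissue_model()].
#' @return a [binary_mask()], the union of GM and WM.
#' @export
tissue_brain_mask <- function(tissue) mask_union(tissue$gm_mask, tissue$wm_mask)

#' Generate a synthetic normative cohort
#'
#' Draws `n_subjects` resting-state runs on one grid. The generating model
#' for voxel v of subject s at time t is
#' \deqn{x_{v}(t) = a_v \, \ell_{k(v)}(t) + g(t) + \epsilon_v(t)}
#' where \eqn{\ell_k} is the latent time-course of the network containing v
#' (i.i.d. Gaussian, sd `timecourse_sd`; absent for non-member voxels),
#' \eqn{a_v} is 1 in GM and `wm_signal_scale` in WM, \eqn{g} is the optional
#' brain-wide shared signal (sd `global_signal_sd`), and \eqn{\epsilon_v} is
#' white Gaussian noise with the tissue's sd. Voxels outside the brain are 0.
#'
#' Because everything is white Gaussian, expected correlations are available
#' in closed form, e.g. between two GM members of one network
#' \deqn{\rho = (s^2 + \gamma^2) / (s^2 + \gamma^2 + \sigma^2)}
#' with `s = timecourse_sd`, `gamma = global_signal_sd`,
#' `sigma = gm_noise_sd`, reducing to \eqn{s^2/(s^2+\sigma^2)} without the
#' global component.
#'
#' @param grid a [template_grid()].
#' @param networks list of pairwise disjoint [planted_network()]s inside the
#'   brain mask.
#' @param tissue a [tissue_model()].
#' @param n_subjects number of runs to draw.
#' @param n_timepoints timepoints per run (>= 30 recommended).
#' @param rng_seed integer seed; generation is bit-reproducible from it.
#' @return object of class `synthetic_cohort`: list with `runs` (list of
#'   [bold_run()]), `atlas` (the planted networks), `tissue`, `rng_seed`.
#' @export
make_normative_cohort <- function(grid, networks, tissue, n_subjects,
                                  n_timepoints, rng_seed) {
  stopifnot(inherits(grid, "template_grid"), inherits(tissue, "tissue_model"))
  if (n_subjects < 1L) stop("`n_subjects` must be positive")
  if (n_timepoints < 2L) stop("`n_timepoints` must be >= 2")
  brain <- tissue_brain_mask(tissue)
  stop_if_grid_mismatch(grid, brain$grid, "grid and tissue masks")
  cover <- array(0, dim = grid$shape)
  for (nw in networks) {
    stopifnot(inherits(nw, "planted_network"))
    stop_if_grid_mismatch(grid, nw$spatial_map$grid, "grid and network map")
    if (any(nw$spatial_map$values > brain$values))
      stop("network '", nw$name, "' extends outside the brain mask")
    cover <- cover + nw$spatial_map$values
  }
  if (any(cover > 1)) stop("planted networks must be pairwise disjoint")

  sh <- grid$shape
  n_vox <- prod(sh)
  brain_lin <- which(brain$values == 1)
  gm_lin <- which(tissue$gm_mask$values == 1)
  wm_lin <- which(tissue$wm_mask$values == 1)
  noise_sd_vec <- numeric(n_vox)
  noise_sd_vec[gm_lin] <- tissue$gm_noise_sd
  noise_sd_vec[wm_lin] <- tissue$wm_noise_sd
  amp_vec <- numeric(n_vox)
  amp_vec[gm_lin] <- 1
  amp_vec[wm_lin] <- tissue$wm_signal_scale
  member_of <- integer(n_vox)                     # 0 = no network
  for (q in seq_along(networks))
    member_of[which(networks[[q]]$spatial_map$values == 1)] <- q

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(rng_seed))
  runs <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    flat <- matrix(0, nrow = n_vox, ncol = n_timepoints)
    flat[brain_lin, ] <- stats::rnorm(length(brain_lin) * n_timepoints) *
      noise_sd_vec[brain_lin]
    if (tissue$global_signal_sd > 0) {
      g <- stats::rnorm(n_timepoints, sd = tissue$global_signal_sd)
      flat[brain_lin, ] <- flat[brain_lin, ] + rep(g, each = length(brain_lin))
    }
    for (q in seq_along(networks)) {
      lat <- stats::rnorm(n_timepoints, sd = networks[[q]]$timecourse_sd)
      mem <- which(member_of == q)
      flat[mem, ] <- flat[mem, ] + outer(amp_vec[mem], lat)
    }
    runs[[s]] <- bold_run(array(flat, dim = c(sh, n_timepoints)), grid, brain)
  }
  structure(list(runs = runs, atlas = networks, tissue = tissue,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$runs), " subjects, ",
      x$runs[[1L]]$n_timepoints, " timepoints, ",
      length(x$atlas), " planted networks, seed ", x$rng_seed, "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic lesion straddling GM and WM
#'
#' Samples `n_gm_voxels` uniformly from the intersection of the target
#' network with GM (the coherent-signal compartment) and `n_wm_voxels` from
#' WM outside that network (incoherent noise voxels), emulating the typical
#' stroke lesion that hits both compartments. Deterministic given the seed.
#'
#' @param grid a [template_grid()].
#' @param tissue a [tissue_model()].
#' @param network the [planted_network()] the lesion overlaps.
#' @param n_gm_voxels,n_wm_voxels voxel counts per compartment.
#' @param rng_seed integer seed.
#' @return a [binary_mask()] lesion.
#' @export
make_lesion <- function(grid, tissue, network, n_gm_voxels, n_wm_voxels,
                        rng_seed) {
  stopifnot(inherits(tissue, "tissue_model"), inherits(network, "planted_network"))
  gm_pool <- which(tissue$gm_mask$values * network$spatial_map$values == 1)
  wm_pool <- which(tissue$wm_mask$values * (1 - network$spatial_map$values) == 1)
  if (n_gm_voxels > length(gm_pool))
    stop("requested ", n_gm_voxels, " GM voxels but only ", length(gm_pool),
         " available in network ∩ GM")
  if (n_wm_voxels > length(wm_pool))
    stop("requested ", n_wm_voxels, " WM voxels but only ", length(wm_pool),
         " available")
  if (n_gm_voxels + n_wm_voxels < 1L) stop("lesion must have >= 1 voxel")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(rng_seed))
  pick <- c(if (n_gm_voxels > 0) sample(gm_pool, n_gm_voxels),
            if (n_wm_voxels > 0) sample(wm_pool, n_wm_voxels))
  arr <- array(0, dim = grid$shape)
  arr[pick] <- 1
  binary_mask(arr, grid)
}

#' Generate behaviour scores from disconnection maps
#'
#' Each subject's score is the voxelwise dot product of their disconnection
#' map with a fixed weight map, plus Gaussian noise:
#' \eqn{y_i = \sum_v w(v)\, m_i(v) + \mathcal{N}(0, \sigma^2)}.
#' The true weights and noise sd are attached as attributes so recovery can
#' be checked.
#'
#' @param disconnection_maps list of `network_map` or [volume3d()] objects,
#'   one per subject, on one grid.
#' @param weight_map a [volume3d()] of true voxel weights.
#' @param noise_sd non-negative noise standard deviation.
#' @param rng_seed integer seed.
#' @return a [tibble::tibble()] with columns `subject`, `score`; attributes
#'   `weight_map`, `noise_sd`, `true_score` carry the generation metadata.
#' @export
make_behaviour <- function(disconnection_maps, weight_map, noise_sd, rng_seed) {
  stopifnot(inherits(weight_map, "volume3d"), noise_sd >= 0)
  vals <- vapply(disconnection_maps, function(m) {
    v <- if (inherits(m, "network_map")) m else m
    stop_if_grid_mismatch(v$grid, weight_map$grid, "map and weight map")
    sum(v$values * weight_map$values)
  }, numeric(1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(rng_seed))
  scores <- vals + stats::rnorm(length(vals), sd = noise_sd)
  out <- tibble::tibble(subject = sprintf("sub%03d", seq_along(vals)),
                        score = scores)
  attr(out, "weight_map") <- weight_map
  attr(out, "noise_sd") <- noise_sd
  attr(out, "true_score") <- vals
  out
}

# save/restore the global RNG state so generator seeding is hermetic
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Canned synthetic study conditions
#'
#' One-call constructor of the scaled-down synthetic study used throughout
#' the package's tests, examples and reproduction script: a cubic 2 mm grid
#' split into a GM compartment (lower half along axis 1) and a WM compartment
#' (upper half), three disjoint planted networks in GM, latent sd 1, noise sd
#' 1 in both tissues, `wm_signal_scale = 0.35` and a weak global signal
#' (`global_signal_sd = 0.3`).
#'
#' @param n grid side length (voxels).
#' @param n_subjects,n_timepoints cohort dimensions.
#' @param rng_seed integer seed.
#' @param global_signal_sd brain-wide shared-signal sd.
#' @return a `synthetic_cohort` (see [make_normative_cohort()]).
#' @export
demo_cohort <- function(n = 12, n_subjects = 12, n_timepoints = 150,
                        rng_seed = 1, global_signal_sd = 0.3) {
  if (n < 12) stop("`demo_cohort` needs a grid side of at least 12 voxels")
  grid <- template_grid(c(n, n, n))
  half <- n %/% 2L
  gm_arr <- array(0, dim = grid$shape); gm_arr[1:half, , ] <- 1
  wm_arr <- array(0, dim = grid$shape); wm_arr[(half + 1L):n, , ] <- 1
  gm <- binary_mask(gm_arr, grid)
  wm <- binary_mask(wm_arr, grid)
  tissue <- tissue_model(gm, wm, gm_noise_sd = 1, wm_noise_sd = 1,
                         wm_signal_scale = 0.35,
                         global_signal_sd = global_signal_sd)
  # three disjoint GM blocks, each half x 4 x 2 voxels
  block <- function(jr, kr) {
    arr <- array(0, dim = grid$shape)
    arr[1:half, jr, kr] <- 1
    binary_mask(arr, grid)
  }
  networks <- list(
    planted_network("netA", block(1:4, 1:2)),
    planted_network("netB", block(5:8, 4:5)),
    planted_network("netC", block(9:12, 7:8)))
  make_normative_cohort(grid, networks, tissue, n_subjects, n_timepoints,
                        rng_seed)
}

#' Write a synthetic cohort to disk
#'
#' Materializes runs, tissue masks, atlas maps and (optionally) a behaviour
#' table as NIfTI / TSV files, the on-disk layout the command-line interface
#' consumes.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @param behaviour optional behaviour tibble from [make_behaviour()].
#' @return named list of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, behaviour = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "bold"), showWarnings = FALSE)
  dir.create(file.path(dir, "atlas"), showWarnings = FALSE)
  paths <- list()
  paths$brain_mask <- file.path(dir, "brain_mask.nii.gz")
  write_volume(tissue_brain_mask(cohort$tissue), paths$brain_mask)
  paths$gm_mask <- file.path(dir, "gm_mask.nii.gz")
  write_volume(cohort$tissue$gm_mask, paths$gm_mask)
  paths$wm_mask <- file.path(dir, "wm_mask.nii.gz")
  write_volume(cohort$tissue$wm_mask, paths$wm_mask)
  paths$bold <- vapply(seq_along(cohort$runs), function(s) {
    p <- file.path(dir, "bold", sprintf("sub%03d.nii.gz", s))
    write_bold(cohort$runs[[s]], p)
    p
  }, character(1))
  paths$atlas <- vapply(cohort$atlas, function(nw) {
    p <- file.path(dir, "atlas", paste0(nw$name, ".nii.gz"))
    write_volume(nw$spatial_map, p)
    p
  }, character(1))
  if (!is.null(behaviour)) {
    paths$behaviour <- file.path(dir, "behaviour.tsv")
    utils::write.table(as.data.frame(behaviour[, c("subject", "score")]),
                       paths$behaviour, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}
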