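# Synthetic phantoms and cohorts: CT-like volumes with haematoma, oedema and
# ventricular blood blobs at realistic Hounsfield intensities, slice-thickness
# acquisition batches, injectable feature-space batch effects, clinical
# covariates, and outcomes drawn from a known generative model. Everything is
# a pure function of (spec, seed).

#' Phantom specification
#'
#' Tissue intensities default to standard CT ranges: brain parenchyma
#' 30 +/- 5 HU, acute haematoma 65 +/- 8 HU, perihaematomal oedema
#' 18 +/- 4 HU, CSF 8 +/- 3 HU; air surrounds the head at -1000 HU.
#'
#' @param brain_semiaxes_mm brain ellipsoid semi-axes (mm).
#' @param haematoma_radius_mm haematoma sphere radius (mm).
#' @param oedema_thickness_mm oedema shell thickness around the haematoma.
#' @param ivh include an intraventricular blood blob.
#' @param ivh_radius_mm IVH blob radius (mm).
#' @param hu_mean,hu_sd named tissue intensity means and noise SDs (HU).
#' @param slice_thickness_mm acquired slice thickness (1, 3 or 5 mm
#'   emulate the three acquisition batches).
#' @param seed RNG seed.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(brain_semiaxes_mm = c(52, 62, 45),
                         haematoma_radius_mm = 15,
                         oedema_thickness_mm = 4,
                         ivh = FALSE, ivh_radius_mm = 6,
                         hu_mean = c(brain = 30, haematoma = 65,
                                     oedema = 18, csf = 8),
                         hu_sd = c(brain = 5, haematoma = 8,
                                   oedema = 4, csf = 3),
                         slice_thickness_mm = 5, seed = 1L) {
  if (any(hu_sd < 0)) stop("phantom_spec: noise SDs must be >= 0")
  if (haematoma_radius_mm + oedema_thickness_mm >= min(brain_semiaxes_mm))
    stop("phantom_spec: haematoma (plus oedema) exceeds the brain envelope")
  structure(as.list(environment()), class = "phantom_spec")
}

#' Generate a CT phantom and its region mask
#'
#' Builds a 1-mm grid, paints tissue blobs with additive Gaussian noise,
#' then simulates acquisition by averaging consecutive z-slices to the
#' requested slice thickness (labels by per-slab majority vote) and storing
#' anisotropic spacing.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` ([volume_grid]) and `mask` ([region_mask]).
#' @export
generate_phantom <- function(spec) {
  set.seed(spec$seed)
  ax <- spec$brain_semiaxes_mm
  margin <- 4
  d <- as.integer(ceiling(2 * ax + 2 * margin))
  ctr <- (d + 1) / 2
  xs <- (seq_len(d[1]) - ctr[1]); ys <- (seq_len(d[2]) - ctr[2])
  zs <- (seq_len(d[3]) - ctr[3])
  X <- array(xs, d); Y <- array(rep(ys, each = d[1]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  brain <- (X / ax[1])^2 + (Y / ax[2])^2 + (Z / ax[3])^2 <= 1
  vent <- (X / 9)^2 + (Y / 18)^2 + (Z / 10)^2 <= 1
  r_h <- spec$haematoma_radius_mm
  reach <- r_h + spec$oedema_thickness_mm + 2
  hc <- NULL
  for (try in 1:100) {
    cand <- stats::runif(3, -0.5, 0.5) * (ax - reach)
    if (sum((abs(cand) + reach)^2 / ax^2) <= 1) { hc <- cand; break }
  }
  if (is.null(hc)) stop("generate_phantom: could not place haematoma inside brain")
  dist_h <- sqrt((X - hc[1])^2 + (Y - hc[2])^2 + (Z - hc[3])^2)
  ich <- dist_h <= r_h
  phe <- dist_h <= r_h + spec$oedema_thickness_mm & !ich & brain & !vent
  ivh <- array(FALSE, d)
  if (isTRUE(spec$ivh)) {
    dv <- sqrt(X^2 + (Y - 6)^2 + Z^2)
    ivh <- dv <= spec$ivh_radius_mm & vent
  }
  ich <- ich & brain
  vol <- array(-1000, d)
  mu <- spec$hu_mean; sd_ <- spec$hu_sd
  paint <- function(vol, where, tissue) {
    n <- sum(where)
    vol[where] <- mu[[tissue]] + stats::rnorm(n, 0, sd_[[tissue]])
    vol
  }
  vol <- paint(vol, brain, "brain")
  vol <- paint(vol, vent, "csf")
  vol <- paint(vol, phe, "oedema")
  vol <- paint(vol, ich | ivh, "haematoma")
  labels <- array(0L, d)
  labels[phe] <- 3L; labels[ivh] <- 2L; labels[ich] <- 1L
  th <- as.integer(round(spec$slice_thickness_mm))
  if (th > 1) {
    nz <- (d[3] %/% th) * th
    grp <- rep(seq_len(nz %/% th), each = th)
    vslab <- array(0, c(d[1], d[2], nz %/% th))
    lslab <- array(0L, c(d[1], d[2], nz %/% th))
    for (g in seq_len(nz %/% th)) {
      zi <- which(grp == g)
      vslab[, , g] <- apply(vol[, , zi, drop = FALSE], c(1, 2), mean)
      lslab[, , g] <- apply(labels[, , zi, drop = FALSE], c(1, 2), function(v) {
        tb <- tabulate(v + 1L, nbins = 4L)
        which.max(tb) - 1L
      })
    }
    vol <- vslab; labels <- lslab
  }
  sp <- c(1, 1, th)
  list(volume = volume_grid(vol, sp),
       mask = region_mask(labels, sp))
}

#' Cohort specification
#'
#' Defaults mirror the study population scale: age normal with mean 69 and
#' SD 13 years, 56% male, 1:1 treatment allocation, three slice-thickness
#' acquisition batches, haematoma-expansion prevalence calibrated to 0.27
#' and poor-functional-outcome prevalence to 0.50.
#'
#' @param n subjects.
#' @param p features in the feature-level generator.
#' @param n_informative features carrying outcome signal.
#' @param beta_growth per-informative-feature coefficient in the log-growth
#'   model.
#' @param beta_outcome per-informative-feature log-odds coefficient for poor
#'   outcome.
#' @param v0_beta_growth coefficient of standardised log baseline volume in
#'   the log-growth model (larger haematomas expand more).
#' @param age_beta_outcome log-odds per year of age (poor outcome).
#' @param duplicate_block,duplicate_r size and pairwise correlation of a
#'   near-duplicate feature block (exercises the correlation filter).
#' @param batch_props proportions over the thickness batches (1, 3, 5 mm).
#' @param batch_shift,batch_scale injectable per-batch location/scale batch
#'   effects on features.
#' @param age_mean,age_sd,male_prop,treatment_prop,antiplatelet_prop
#'   clinical covariate distributions.
#' @param expansion_prevalence,poor_outcome_prevalence calibration targets.
#' @param growth_sd SD of the log-growth model.
#' @param seed RNG seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n = 500L, p = 50L, n_informative = 5L,
                        beta_growth = 0.3, beta_outcome = 1.0,
                        v0_beta_growth = 0.15, age_beta_outcome = 0.05,
                        duplicate_block = 5L, duplicate_r = 0.95,
                        batch_props = c(0.2, 0.3, 0.5),
                        batch_shift = c(0, 0, 0), batch_scale = c(1, 1, 1),
                        age_mean = 69, age_sd = 13, male_prop = 0.56,
                        treatment_prop = 0.5, antiplatelet_prop = 0.25,
                        expansion_prevalence = 0.27,
                        poor_outcome_prevalence = 0.50,
                        growth_sd = 0.45, seed = 1L) {
  stopifnot(abs(sum(batch_props) - 1) < 1e-8, all(batch_props >= 0),
            all(batch_scale > 0))
  structure(as.list(environment()), class = "cohort_spec")
}

#' Inject location-scale batch effects into a feature table
#'
#' `x -> scale_b * x + shift_b` per subject's batch, applied after an
#' optional feature-noise draw.
#'
#' @param table subjects x features matrix.
#' @param batches batch index per subject (1-based into shift/scale).
#' @param shift,scale per-batch location shifts and scale factors
#'   (scale > 0).
#' @param noise_sd optional iid noise added before the batch transform.
#' @param seed optional seed for the noise draw.
#' @return transformed matrix.
#' @export
inject_batch_effects <- function(table, batches, shift, scale,
                                 noise_sd = 0, seed = NULL) {
  if (any(scale <= 0)) stop("inject_batch_effects: scale factors must be > 0")
  X <- as.matrix(table)
  b <- as.integer(batches)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    X <- X + stats::rnorm(length(X), 0, noise_sd)
  }
  X * scale[b] + shift[b]
}

.calibrate_intercept <- function(prob_fun, target, lower = -30, upper = 30) {
  f <- function(b) mean(prob_fun(b)) - target
  if (f(lower) > 0 || f(upper) < 0)
    stop("simulate_outcomes: unattainable target prevalence ", target)
  stats::uniroot(f, c(lower, upper), tol = 1e-8)$root
}

#' Simulate outcomes from a known generative model
#'
#' Haematoma growth: `v24 = v0 * exp(g)` with
#' `g ~ Normal(mu + x' beta_g, sigma_g^2)`; the expansion label follows the
#' clinical definition (> 6 mL or > 33%). Poor functional outcome:
#' `Bernoulli(logistic(b0 + x' beta_o + age effect))`. The intercepts `mu`
#' and `b0` are calibrated by root finding so the expected prevalences hit
#' the spec targets.
#'
#' @param features subjects x features matrix (informative columns are the
#'   first `spec$n_informative` after the duplicate block).
#' @param spec a [cohort_spec()].
#' @param clinical data.frame with `v0_ml`, `onset_to_scan_h`, `age`.
#' @return data.frame of per-subject outcomes (`v0_ml`, `v24_ml`,
#'   `expansion`, `mrs_day90`, `poor_outcome`, `ultra_early_growth`).
#' @export
simulate_outcomes <- function(features, spec, clinical) {
  X <- as.matrix(features)
  info <- spec$duplicate_block + seq_len(spec$n_informative)
  if (max(info) > ncol(X))
    stop("simulate_outcomes: informative feature ids outside the table")
  xb_g <- as.numeric(X[, info, drop = FALSE] %*%
                       rep(spec$beta_growth, spec$n_informative)) +
    spec$v0_beta_growth * as.numeric(scale(log(clinical$v0_ml)))
  xb_o <- as.numeric(X[, info, drop = FALSE] %*%
                       rep(spec$beta_outcome, spec$n_informative)) +
    spec$age_beta_outcome * (clinical$age - spec$age_mean)
  v0 <- clinical$v0_ml
  thr <- log(1 + pmin(6 / v0, 0.33))
  mu <- .calibrate_intercept(
    function(b) 1 - stats::pnorm((thr - b - xb_g) / spec$growth_sd),
    spec$expansion_prevalence)
  g <- stats::rnorm(nrow(X), mu + xb_g, spec$growth_sd)
  v24 <- v0 * exp(g)
  expansion <- label_haematoma_expansion(v0, v24)
  b0 <- .calibrate_intercept(function(b) plogis(b + xb_o),
                             spec$poor_outcome_prevalence)
  p_poor <- plogis(b0 + xb_o)
  poor <- stats::rbinom(nrow(X), 1, p_poor) == 1
  mrs <- ifelse(poor, sample(4:6, nrow(X), replace = TRUE),
                sample(0:3, nrow(X), replace = TRUE))
  data.frame(v0_ml = v0, v24_ml = v24, expansion = expansion,
             mrs_day90 = mrs, poor_outcome = poor,
             ultra_early_growth = ultra_early_growth(v0, clinical$onset_to_scan_h))
}

#' Generate a synthetic cohort
#'
#' The fast feature-level cohort draws correlated Gaussian features (a
#' near-duplicate block for correlation-filter tests, then independent
#' informative and noise features), clinical covariates, slice-thickness
#' batches (with optional injected location-scale batch effects) and
#' outcomes from the generative model. The image-level cohort pushes
#' phantoms through the real extraction path instead (slow; intended for
#' small n) and shares the clinical/outcome schema.
#'
#' @param spec a [cohort_spec()].
#' @param level `"feature"` (default) or `"image"`.
#' @return list with `features` (matrix), `clinical` (data.frame incl.
#'   batch, signs), `outcomes` (data.frame) and `spec`.
#' @export
generate_cohort <- function(spec, level = c("feature", "image")) {
  level <- match.arg(level)
  set.seed(spec$seed)
  n <- spec$n
  thickness <- c(1, 3, 5)[sample.int(3, n, replace = TRUE,
                                     prob = spec$batch_props)]
  clinical <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = stats::rnorm(n, spec$age_mean, spec$age_sd),
    gender = ifelse(stats::rbinom(n, 1, spec$male_prop) == 1, "male", "female"),
    treatment = stats::rbinom(n, 1, spec$treatment_prop),
    antiplatelet = stats::rbinom(n, 1, spec$antiplatelet_prop),
    slice_thickness_mm = thickness,
    batch = assign_batch(thickness),
    v0_ml = stats::rlnorm(n, log(12), 0.85),
    onset_to_scan_h = stats::rlnorm(n, log(2), 0.5))
  if (level == "image") {
    feats <- NULL
    for (i in seq_len(n)) {
      ps <- phantom_spec(haematoma_radius_mm = stats::runif(1, 10, 18),
                         ivh = stats::runif(1) < 0.3,
                         slice_thickness_mm = thickness[i],
                         seed = spec$seed * 1000L + i)
      ph <- generate_phantom(ps)
      fv <- extract_subject(ph$volume, ph$mask, clinical[i, ])
      if (is.null(feats))
        feats <- matrix(NA_real_, n, length(fv), dimnames = list(NULL, names(fv)))
      feats[i, ] <- fv
    }
    clinical$v0_ml <- feats[, "Intracerebral haemorrhage volume (voxel, mL)"]
    # outcome signal: standardised copies of the first informative radiomics
    # columns, laid out where simulate_outcomes expects them
    sds <- apply(feats, 2, stats::sd)
    src <- which(sds > 0)[seq_len(spec$n_informative)]
    sig <- matrix(0, n, spec$duplicate_block + spec$n_informative)
    sig[, spec$duplicate_block + seq_len(spec$n_informative)] <-
      scale(feats[, src, drop = FALSE])
    outcomes <- simulate_outcomes(sig, spec, clinical)
  } else {
    p <- spec$p
    u <- stats::rnorm(n)
    feats <- matrix(stats::rnorm(n * p), n, p)
    r <- spec$duplicate_r
    if (spec$duplicate_block > 0)
      for (j in seq_len(spec$duplicate_block))
        feats[, j] <- sqrt(r) * u + sqrt(1 - r) * feats[, j]
    colnames(feats) <- sprintf("feat_%03d", seq_len(p))
    outcomes <- simulate_outcomes(feats, spec, clinical)
  }
  clinical$blend_sign <- stats::rbinom(n, 1, ifelse(outcomes$expansion, 0.24, 0.12))
  clinical$black_hole_sign <- stats::rbinom(n, 1, ifelse(outcomes$expansion, 0.22, 0.13))
  clinical$hypodensities <- stats::rbinom(n, 1, ifelse(outcomes$expansion, 0.38, 0.22))
  clinical$island_sign <- stats::rbinom(n, 1, ifelse(outcomes$expansion, 0.11, 0.05))
  if (any(spec$batch_shift != 0) || any(spec$batch_scale != 1))
    feats <- inject_batch_effects(feats, clinical$batch, spec$batch_shift,
                                  spec$batch_scale)
  list(features = feats, clinical = clinical, outcomes = outcomes, spec = spec)
}
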