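# Small geometric fixtures built in code.

make_grid <- function(values, dims, spacing = c(1, 1, 1)) {
  volume_grid(array(values, dims), spacing)
}

make_mask <- function(labels, dims, spacing = c(1, 1, 1)) {
  region_mask(array(as.integer(labels), dims), spacing)
}

# digital ball of radius r (voxels) centred in a cube with 2-voxel margin
digital_ball <- function(r) {
  n <- 2L * ceiling(r) + 5L
  ctr <- (n + 1) / 2
  idx <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  inside <- colSums((t(idx) - ctr)^2) <= r^2
  make_mask(as.integer(inside), c(n, n, n))
}

# random discretised ROI on a small grid: levels 1..ng inside a random blob
random_roi <- function(seed, dims = c(6, 6, 6), ng = 4) {
  set.seed(seed)
  lev <- array(sample.int(ng, prod(dims), replace = TRUE), dims)
  inroi <- array(runif(prod(dims)) < 0.8, dims)
  lev[!inroi] <- 0L
  if (!any(lev > 0)) lev[1] <- 1L
  structure(list(levels = array(as.integer(lev), dims), Ng = as.integer(ng),
                 Ng_effective = length(unique(lev[lev > 0])),
                 bin_edges = 0:ng, values = as.numeric(lev[lev > 0]),
                 spacing = c(1, 1, 1)),
            class = "discretised_roi")
}

# a tiny clinical row for extract_subject
clin_row <- function(th = 5) {
  list(subject_id = "T1", slice_thickness_mm = th, age = 70,
       gender = "male", treatment = 1)
}
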