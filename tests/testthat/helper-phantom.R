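# Small phantom configurations used throughout the suite. Grids are kept
# modest (48x48x14 at 1.25 mm in-plane / 3 mm slices) so geometric
# properties are testable at interactive speed; the gland has its absolute
# anatomical size, and the 60 x 60 x 42 mm field of view leaves headroom
# for misalignments up to the full augmentation bounds without truncating
# the gland at the volume boundary.

tiny_phantom_config <- function(seed = 1, n_lesions = 2, noise = 0.05,
                                misalign = NULL,
                                grid = c(48, 48, 14),
                                spacing = c(1.25, 1.25, 3)) {
  phantom_config(grid_shape = grid, spacing = spacing, n_lesions = n_lesions,
                 lesion_radius_range = c(3.5, 5), noise_sigma = noise,
                 true_misalignment = misalign, seed = seed)
}

tiny_exam <- function(...) generate_phantom(tiny_phantom_config(...))

# brute-force Mann-Whitney AUROC used as the exhaustive pairwise oracle
auroc_oracle <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
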