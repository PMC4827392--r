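# Shared phantom configurations for tests. Small variants of the default
# phantom keep unit tests fast; the default-scale spec is used where a test
# exercises the study conditions themselves.

tiny_spec <- function(...) {
  args <- list(grid_shape = c(8L, 8L, 8L),
               component_centers_x = rbind(c(2, 2, 2), c(5, 2, 4), c(2, 5, 5)),
               component_centers_y = rbind(c(5, 5, 2), c(2, 4, 5), c(5, 5, 5)),
               blob_sigma = 1, smoothing_fwhm = 2,
               subjects_per_group = c(4L, 4L, 4L),
               mask_radius = 3.8, seed = 42L)
  over <- list(...)
  do.call(phantom_spec, c(over, args[!names(args) %in% names(over)]))
}

# Two-group phantom with a single separating component at a prescribed
# standardized group difference d on component 1 (loading_sd = 1).
two_group_spec <- function(d, subjects_per_group, seed, ...) {
  phantom_spec(group_means = rbind(MCIs = c(d / 2, 0, 0),
                                   MCIc = c(-d / 2, 0, 0)),
               subjects_per_group = subjects_per_group,
               seed = seed, ...)
}

# Coincident-component variant: Y components at the X locations, making all
# planted correlations purely local.
coincident_spec <- function(...) {
  spec <- phantom_spec(...)
  spec$component_centers_y <- spec$component_centers_x
  spec
}
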