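# Shared fixtures: small synthetic configurations sized for fast tests.

tile_synth_config <- function(seed = 42L, lesion_class = "EX",
                              size = 64L, ...) {
  defaults <- list(image_height = size, image_width = size,
                   disc_radius_fraction = 0.5, vessel_count = 2L,
                   lesion_class = lesion_class,
                   lesion_count_range = c(1L, 3L),
                   lesion_radius_range = c(3, 7),
                   noise_sigma = 3, seed = seed)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

small_model <- function(depth = 1L, base_channels = 9L, seed = 1L, ...) {
  build_ffunet(ffunet_config(depth = depth, base_channels = base_channels, ...),
               seed = seed)
}

# normalized training tiles from the synthetic generator
make_tiles <- function(n = 8L, seed = 42L, size = 64L, ...) {
  ds <- generate_dataset(n, tile_synth_config(seed = seed, size = size, ...),
                         negative_fraction = 0.25)
  stats <- compute_dataset_stats(lapply(ds, function(d) d$image))
  list(tiles = lapply(ds, function(d)
         list(image = normalize_image(d$image, stats)$pixels,
              mask = d$mask$pixels)),
       stats = stats, raw = ds)
}
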