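# Coarse-grid phantom spec used throughout the unit tests: same anatomy as
# the default (40 mm limb radius over a 192 mm axis) on a 48^3 grid with
# 4 mm voxels, which keeps per-phantom generation well under a second.
small_phantom_spec <- function(...) {
  phantom_spec(dims = c(48L, 48L, 48L), spacing = c(4, 4, 4), ...)
}

# A bare soft-tissue cylinder CT (uniform fat, no bone or muscle) built
# directly, bypassing the phantom generator.
fat_cylinder_ct <- function(dims = c(24L, 24L, 24L), spacing = c(4, 4, 4),
                            radius_mm = 36, hu = -100) {
  vox <- array(-1000, dims)
  r2 <- outer((seq_len(dims[1]) - (dims[1] + 1) / 2)^2 * spacing[1]^2,
              (seq_len(dims[2]) - (dims[2] + 1) / 2)^2 * spacing[2]^2, `+`)
  for (k in seq_len(dims[3])) vox[, , k][r2 <= radius_mm^2] <- hu
  image_volume(vox, spacing, "CT")
}
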