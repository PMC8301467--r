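# Shared lazily-built phantom fixtures. Coarse voxel sizes keep the default
# suite fast; the acceptance tests build their own finer phantoms.

.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(key, builder) {
  if (!exists(key, envir = .phantom_cache))
    assign(key, builder(), envir = .phantom_cache)
  get(key, envir = .phantom_cache)
}

rat_both_015 <- function() cached_phantom("rat_both_015", function()
  make_phantom(phantom_spec("rat", voxel_mm = 0.15)))

rat_left_012 <- function() cached_phantom("rat_left_012", function()
  make_phantom(phantom_spec("rat", voxel_mm = 0.12, sides = "left")))

rat_left_030 <- function() cached_phantom("rat_left_030", function()
  make_phantom(phantom_spec("rat", voxel_mm = 0.3, sides = "left")))

rabbit_both_020 <- function() cached_phantom("rabbit_both_020", function()
  make_phantom(phantom_spec("rabbit", voxel_mm = 0.2)))

# small solid-bone block with phantom geometry metadata, for analytic
# defect-volume checks (the sphere must lie entirely inside bone)
bone_block <- function(voxel = 0.1) {
  nx <- round(10 / voxel); ny <- round(10 / voxel); nz <- round(10 / voxel)
  vol <- volume(array(1000, c(nx, ny, nz)), voxel,
                c(voxel / 2, -10 + voxel / 2, voxel / 2))
  attr(vol, "phantom_geometry") <- list(
    spec_species = "rat",
    geometry = list(gap = 1, body_w = 9, body_y = c(0, 10), body_z = c(0, 10),
                    ramus_y = c(-10, 0), ramus_z = c(0, 10),
                    molars = list(y_center = c(4, 6))),
    sides = "left")
  vol
}
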