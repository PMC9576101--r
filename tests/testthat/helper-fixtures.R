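# shared fixtures: the packaged material library and forward-modelled ROIs

lib <- material_library()

# noise-free ROI summaries generated by the forward model at energy E0,
# optionally distorted by an affine HU miscalibration
forward_rois <- function(materials, E0, gain = 1, offset = 0,
                         library = lib) {
  rows <- lapply(materials, function(m)
    roi_sample(m, gain * predicted_hu(m, E0, library) + offset,
               sd_hu = 0, n_voxels = 100))
  do.call(roi_samples, rows)
}

# forward water-equivalent density of a material at E0 (the closed-form truth)
weq_density <- function(material, E0, library = lib) {
  library[[material]]$rho_ref *
    mass_attenuation(library[[material]], E0) /
    mass_attenuation(library$water, E0)
}

# small scene: the default synthetic scan scenario at modest size
tiny_scene <- function(...) default_scan_scenario(...)
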