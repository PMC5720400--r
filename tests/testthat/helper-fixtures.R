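# Shared fixtures: everything is generated in code at test time.

# full bench geometry (the study conditions)
bench_geometry <- function(n_views = 360L) {
  cone_beam_geometry(sad = 1000, sdd = 1500, det_size_u = 300, det_size_v = 300,
                     n_u = 128L, n_v = 128L, n_views = n_views)
}

# small geometry for fast unit tests (same SAD/SDD and panel size)
tiny_geometry <- function(n_u = 32L, n_v = 32L, n_views = 24L) {
  cone_beam_geometry(n_u = n_u, n_v = n_v, n_views = n_views)
}

# uniform cylinder in air with a given mu (1/cm)
uniform_cyl <- function(radius = 75, mu = 0.3, half_len = 75) {
  phantom(list(cylinder_element(0, 0, radius, -half_len, half_len,
                                material("uniform", 1, mu = mu))))
}

# a detector mask built directly from v-band intervals (ideal edges),
# for correction tests with hand-placed bands
manual_mask <- function(geometry, open_bands, closed_bands) {
  cc <- detector_coords(geometry)
  open_v <- rep(FALSE, geometry$n_v)
  for (b in seq_len(nrow(open_bands)))
    open_v <- open_v | (cc$v >= open_bands$v_lo[b] & cc$v < open_bands$v_hi[b])
  structure(list(
    values = matrix(as.numeric(open_v), geometry$n_u, geometry$n_v, byrow = TRUE),
    open_bands = open_bands, closed_bands = closed_bands,
    phase = "A", soft_edge_sigma = 0
  ), class = "detector_mask")
}
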