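# Shared simulation products, computed once per test run.  Full rotor
# simulations are expensive; every test that needs one goes through these
# accessors so the movie (or its derived products) is built a single time.
# Grids and durations follow the package's "ci" profile -- the documented
# desk-scale world in which all shipped properties are asserted.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, fun) {
  if (!exists(key, envir = .sim_cache))
    assign(key, fun(), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

fhn_movie <- function() cached("fhn_movie", function() {
  simulate_rotor(cell_model("fhn"), grid_spec(120, 120, 0.5, 1),
                 duration = 650, settle = 300, dt_sample = 1,
                 pacing_cl = 200)
})

crn_movie <- function() cached("crn_movie", function() {
  m <- cell_model("crn", params = af_remodeling())
  simulate_rotor(m, grid_spec(160, 160, 0.025, 3e-4),
                 duration = 1000, settle = 300, dt_sample = 0.5,
                 pacing_cl = 300)
})

crn_tip <- function() cached("crn_tip", function() track_tip(crn_movie()))

# unipolar field of the CRN rotor (far-field kernel); the movie itself is
# released afterwards -- every CRN assertion needs only tip + EGM field
crn_uni <- function(mode = "voltage") cached(paste0("crn_uni_", mode),
                                             function() {
  crn_tip()
  uf <- unipolar_field(crn_movie(), h = 1, source_mode = mode)
  if (exists("crn_movie", envir = .sim_cache))
    rm("crn_movie", envir = .sim_cache)
  gc(verbose = FALSE)
  uf
})

crn_map <- function(s, orientation = "horizontal", mode = "voltage",
                    reference = "per_trace", filter = NULL) {
  key <- paste("crn_map", s, orientation, mode, reference,
               paste(unlist(filter), collapse = "_"), sep = "|")
  cached(key, function() {
    bf <- bipolar_field(crn_uni(mode), s, orientation)
    if (!is.null(filter))
      bf <- apply_filter(bf, do.call(filter_spec, filter))
    shen_map(bf, histogram_spec(reference = reference), c(0.2, 1),
             edge_margin = 5)
  })
}

# LR91 spiral products per Gsi (movie dropped once derived products exist)
lr_products <- function(gsi) cached(paste0("lr_", gsi), function() {
  m <- cell_model("lr91", params = lr_spiral_params(gsi))
  g <- grid_spec(192, 192, 0.025, 3e-4)
  mv <- simulate_rotor(m, g, duration = 700, settle = 200, dt_sample = 1,
                       center = c(96, 120), pacing_cl = 250)
  tip <- track_tip(mv)
  ctr <- round(colMeans(tip$points[, c("x", "y")]))
  uf <- unipolar_field(mv, h = 1, source_mode = "laplacian")
  bf <- bipolar_field(uf, 2, "horizontal")
  map <- shen_map(bf, histogram_spec(reference = "global"), c(0.2, 1),
                  edge_margin = 5)
  scatter <- meridian_direction_scatter(mv, "horizontal", ctr[2],
                                        window = c(0.2, 1))
  shen_line <- map$values[, which.min(abs(map$sites_y - ctr[2]))]
  list(tip = tip, ctr = ctr, map = map, scatter = scatter,
       shen_line = shen_line, nx = g$nx)
})

geo_maps_all <- function() cached("geo_maps", function() {
  geo_bipolar_and_map(geo_spiral_spec(), spacings = c(1, 2, 4, 8, 12, 16),
                      h = 0.25, mesh = 0.25, source_mode = "voltage",
                      hist_spec = histogram_spec(reference = "per_trace"))
})

# analytic planar-wave movie: upstroke ramp moving in +x (or +y) at speed c;
# used where a wave field (not the reaction-diffusion solver) is the input
planar_movie <- function(nx = 60, ny = 60, axis = "x", speed = 1,
                         nt = 80, dt = 1, width = 8, v0 = -80, v1 = 20) {
  fr <- array(v0, c(nx, ny, nt))
  for (k in seq_len(nt)) {
    front <- 5 + speed * (k - 1) * dt
    coord <- if (axis == "x") {
      matrix(seq_len(nx), nx, ny)
    } else {
      matrix(seq_len(ny), nx, ny, byrow = TRUE)
    }
    z <- (front - coord) / width
    fr[, , k] <- v0 + (v1 - v0) * pmin(pmax(z, 0), 1)
  }
  voltage_movie(fr, dt_sample = dt,
                grid_spec(nx, ny, 1, 1, small_ok = TRUE), "planar")
}
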