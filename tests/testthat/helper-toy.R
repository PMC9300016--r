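# Toy-world helpers shared across tests.

# closed-form spherical band cell area (the independent oracle for areas)
band_area <- function(lat1, lat2, dlon_deg, radius = 6371) {
  radius^2 * (dlon_deg * pi / 180) * (sin(lat2 * pi / 180) - sin(lat1 * pi / 180))
}

# a field valid only on `cells` (matrix of (row, col)) of `grid`
sparse_field <- function(grid, cells, values, units = "mg C m-2 day-1") {
  v <- matrix(NA_real_, grid$nlat, grid$nlon)
  v[cells] <- values
  gridded_field(grid, v, units, !is.na(v))
}

# n cells in a single latitude row -> identical (equal) cell areas
row_cells <- function(row, n) cbind(rep(row, n), seq_len(n))

# small per-region table for regional tests
toy_regions <- function(export, fishing, codes = seq_along(export)) {
  data.frame(code = codes, name = paste("R", codes),
             mean_export = export, mean_fishing = fishing)
}

# the published 19-area fixture in region_summary() input layout
fixture_regions <- function() {
  tab <- fao_area_summary()
  data.frame(code = tab$area, name = tab$name,
             mean_export = tab$poc_export, mean_fishing = tab$fishing)
}
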