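# Shared fixtures, built in code at load time.

# the standard synthetic scenario used across modules
std_sim <- simulate_scenario(seed = 42)

# single straight road through a large region: offset-mode nearest distances
# equal the drawn gamma offsets exactly
single_road <- function(width = 200) {
  list(
    region = make_region(width, width),
    roads = road_network(
      data.frame(x0 = 0, y0 = width / 2, x1 = width, y1 = width / 2),
      period_label = "single", map_year = 2000L
    )
  )
}

# small random road network fixture on a unit-free 100 km square
small_network <- function(seed = 7, n_lines = 8) {
  reg <- make_region(100, 100, grid = 4)
  list(region = reg, roads = make_roads(reg, n_lines, seed = seed))
}
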