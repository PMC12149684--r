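# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Coarse (1 mm) head phantom for unit tests: same world extent as the
# default, ~8x fewer voxels.
coarse_grid <- function() grid_spec(c(170L, 120L, 100L), c(1, 1, 1))

coarse_head <- function(seed = 7L) {
  cached(paste0("coarse_head_", seed),
         function() build_head_phantom(coarse_grid(), seed = seed))
}

# Reference WET map chain on the coarse phantom.
coarse_ref_maps <- function() {
  cached("coarse_ref_maps", function() {
    lv <- coarse_head()
    ref <- assign_rsp(lv)
    fine <- project_wet(strip_external_air(ref))
    cg <- map_grid(floor(dim(fine$values) * fine$spacing / c(0.98, 1.5)),
                   c(0.98, 1.5), fine$origin)
    common <- resample_to_grid(fine, grid = cg)
    list(lv = lv, ref = ref, fine = fine, grid = cg, common = common,
         crop = crop_region(common, default_imaged_region(coarse_grid())))
  })
}

# Full default-scale pipeline run (0.5 mm phantom, seed 7); built once and
# shared by the acceptance checks.
default_run <- function() {
  cached("default_run", function() run_pipeline(default_config()))
}

# Small deterministic WET map with structure, for metric/gamma tests.
bumpy_map <- function(n1 = 7L, n2 = 7L, seed = 11L, base = 120) {
  vals <- with_seed_test(seed, matrix(base + 15 * runif(n1 * n2), n1, n2))
  wet_map(vals, spacing = c(1, 1), origin = c(0, 0), provenance = "test")
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  force(code)
}
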