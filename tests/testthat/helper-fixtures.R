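# Shared fixtures, built once per test file and memoised in this
# environment. Coarse meshes keep unit tests fast; the acceptance tests
# build their own full-resolution models.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

circle_contour <- function(r = 1, n = 256L, cx = 0, cy = 0, name = "outer") {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  avianEIT::contour(cbind(cx + r * cos(th), cy + r * sin(th)), name)
}

disk_phantom <- function(mesh_size = 0.07) {
  cached(paste0("disk", mesh_size),
         build_phantom(circle_contour(), mesh_size = mesh_size))
}

test_chicken_phantom <- function(mesh_size = 4) {
  cached(paste0("chick", mesh_size),
         build_phantom(chicken_contours(), mesh_size = mesh_size))
}

test_pattern <- function() cached("pat32", make_pattern(32L, 0L))

test_model <- function(mesh_size = 4) {
  cached(paste0("model", mesh_size),
         train_greit(test_chicken_phantom(mesh_size), test_pattern(),
                     n_targets = 1000L, seed = 11L))
}

# synthetic 32x32 functional image on a rectangular all-true mask
flat_image <- function(values) {
  functional_image(values, matrix(TRUE, 32L, 32L))
}
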