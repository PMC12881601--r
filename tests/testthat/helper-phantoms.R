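# Shared fixtures, generated in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Two-class phantom dataset, 32 px, for classifier/pipeline tests.
phantoms32 <- function(n_per_class = 40L, seed = 42L) {
  key <- sprintf("p32_%d_%d", n_per_class, seed)
  cached(key, {
    spec <- phantom_spec(image_size = 32L)
    generate_dataset(spec, c(normal = n_per_class, abnormal = n_per_class),
                     seed = seed)
  })
}

# Numerical gradient at a handful of coordinates (keeps checks fast).
num_grad_at <- function(f, x, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps
    x2[i] <- x2[i] - eps
    (f(x1) - f(x2)) / (2 * eps)
  }, 0)
}

dummy_samples <- function(n, labels = NULL) {
  lapply(seq_len(n), function(i)
    structure(list(image = array(0.5, c(4, 4, 3)),
                   mask = matrix(0, 4, 4),
                   label = if (is.null(labels)) "a" else labels[i],
                   meta = list(id = i)),
              class = "labeled_sample"))
}
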