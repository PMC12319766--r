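# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# tiny protocol + coarse dictionary for unit tests
tiny_protocol <- function() mrf_protocol(n_groups = 4, trs_per_group = 20)

tiny_setup <- function() {
  cached("tiny", {
    prot <- tiny_protocol()
    dict <- build_dictionary(coarse_grid(), prot)
    basis <- compute_subspace(dict, 5)
    list(protocol = prot, dict = dict, basis = basis,
         cdict = compress_dictionary(dict, basis))
  })
}

# desk-scale protocol + default dictionary (shared by the acceptance tests)
desk_setup <- function() {
  cached("desk", {
    prot <- desk_protocol()
    dict <- build_dictionary(dictionary_grid(), prot)
    basis <- compute_subspace(dict, 5)
    list(protocol = prot, dict = dict, basis = basis,
         cdict = compress_dictionary(dict, basis))
  })
}

rel_err <- function(a, b) {
  sqrt(sum(Mod(a - b)^2)) / max(sqrt(sum(Mod(b)^2)), .Machine$double.eps)
}

# nearest dictionary T1 grid value for each element of x
nearest_grid_t1 <- function(x, t1_grid) {
  g <- sort(unique(t1_grid))
  mid <- (g[-1] + g[-length(g)]) / 2
  g[pmax(1, findInterval(x, mid) + 1)]
}

random_coeffs <- function(dims4, seed = 1) {
  set.seed(seed)
  n <- prod(dims4)
  array(complex(real = rnorm(n), imaginary = rnorm(n)), dims4)
}
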