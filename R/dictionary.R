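# Dictionary construction and temporal subspace basis.

#' Dictionary parameter grid
#'
#' The T1 axis covers 20-3000 ms at a 20 ms step plus a coarse 3200-5000 ms
#' extension at a 200 ms step for CSF-like values. The default T2 axis spans
#' tissue (10-300 ms, step 10) plus long-T2 fluid values (500-2000 ms, step
#' 100). Only physically valid pairs with T2 <= T1 are simulated.
#'
#' @param t1_values_ms,t2_values_ms Strictly increasing grids in ms.
#' @return An object of class \code{mrf_grid}.
#' @export
dictionary_grid <- function(t1_values_ms = c(seq(20, 3000, by = 20), seq(3200, 5000, by = 200)),
                            t2_values_ms = c(seq(10, 300, by = 10), seq(500, 2000, by = 100))) {
  stop_if(length(t1_values_ms) == 0 || length(t2_values_ms) == 0, "empty grid")
  check_positive(t1_values_ms, "t1_values_ms"); check_positive(t2_values_ms, "t2_values_ms")
  stop_if(is.unsorted(t1_values_ms, strictly = TRUE), "t1_values_ms must be strictly increasing")
  stop_if(is.unsorted(t2_values_ms, strictly = TRUE), "t2_values_ms must be strictly increasing")
  structure(list(t1_values_ms = t1_values_ms, t2_values_ms = t2_values_ms),
            class = "mrf_grid")
}

#' Coarse desk-scale grid
#'
#' Reduced grid for unit-test-sized runs; same structure as the default.
#' @param t1_step,t2_step Step sizes in ms.
#' @return An \code{mrf_grid}.
#' @export
coarse_grid <- function(t1_step = 40, t2_step = 20) {
  dictionary_grid(c(seq(20, 3000, by = t1_step), seq(3200, 5000, by = 200)),
                  c(seq(t2_step, 300, by = t2_step), seq(500, 2000, by = 250)))
}

#' Build the MRF dictionary
#'
#' Simulates one EPG fingerprint per valid (T1, T2) pair of the grid and
#' normalizes each atom to unit Euclidean norm. Atoms are stored as a real
#' matrix: with constant-phase excitation the fingerprints share a global
#' phase, which carries no information for magnitude cross-correlation
#' matching.
#'
#' @param grid An [dictionary_grid()].
#' @param protocol An [mrf_protocol()].
#' @param n_states EPG configuration orders retained.
#' @return Object of class \code{mrf_dictionary} with fields \code{atoms}
#'   (\code{n_atoms x n_timepoints}, rows unit norm), \code{params}
#'   (data.frame of T1/T2 per atom, ordered by T1 then T2), \code{protocol}.
#' @export
build_dictionary <- function(grid, protocol, n_states = 30L) {
  stop_if(!inherits(grid, "mrf_grid"), "grid must be an mrf_grid")
  stop_if(!inherits(protocol, "mrf_protocol"), "protocol must be an mrf_protocol")
  params <- expand.grid(t2 = grid$t2_values_ms, t1 = grid$t1_values_ms)[, c("t1", "t2")]
  params <- params[params$t2 <= params$t1, , drop = FALSE]
  stop_if(nrow(params) == 0, "grid contains no physically valid (T1, T2) pairs")
  params <- params[order(params$t1, params$t2), , drop = FALSE]
  rownames(params) <- NULL
  sig <- epg_core(params$t1, params$t2, protocol, n_states)$signal
  nrm <- sqrt(rowSums(sig^2))
  stop_if(any(nrm == 0), "degenerate zero atom encountered")
  atoms <- sig / nrm
  structure(list(atoms = atoms, params = params, protocol = protocol,
                 n_states = n_states),
            class = "mrf_dictionary")
}

#' @export
print.mrf_dictionary <- function(x, ...) {
  cat(sprintf("MRF dictionary: %d atoms x %d timepoints (T1 %g-%g ms, T2 %g-%g ms)\n",
              nrow(x$atoms), ncol(x$atoms), min(x$params$t1), max(x$params$t1),
              min(x$params$t2), max(x$params$t2)))
  invisible(x)
}

#' Temporal subspace basis of a dictionary
#'
#' Singular value decomposition of the atom matrix; the first \code{k} right
#' (temporal) singular vectors form the subspace basis in which time-resolved
#' images are represented as K coefficient maps.
#'
#' @param dictionary An [build_dictionary()] result.
#' @param k Subspace dimension (default 5).
#' @return Object of class \code{mrf_basis}: \code{phi}
#'   (\code{n_timepoints x k}, orthonormal columns), \code{singular_values},
#'   \code{energy_fraction} (captured squared singular-value energy),
#'   \code{protocol_dims}.
#' @export
compute_subspace <- function(dictionary, k = 5L) {
  stop_if(!inherits(dictionary, "mrf_dictionary"), "dictionary must be an mrf_dictionary")
  A <- dictionary$atoms
  nt <- ncol(A)
  rk <- min(nrow(A), nt)
  stop_if(k < 1 || k > nt, "k must be in [1, n_timepoints]")
  stop_if(k > rk, sprintf("k = %d exceeds the dictionary rank bound %d", k, rk))
  G <- crossprod(A)                      # n_t x n_t, real symmetric
  e <- eigen(G, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  structure(list(
    phi = e$vectors[, seq_len(k), drop = FALSE],
    singular_values = sqrt(ev[seq_len(rk)]),
    energy_fraction = sum(ev[seq_len(k)]) / sum(ev),
    k = as.integer(k),
    n_timepoints = nt
  ), class = "mrf_basis")
}

#' @export
print.mrf_basis <- function(x, ...) {
  cat(sprintf("MRF subspace basis: K = %d over %d timepoints, %.3f%% energy captured\n",
              x$k, x$n_timepoints, 100 * x$energy_fraction))
  invisible(x)
}

#' Persist / load a dictionary with its parameter tables
#'
#' Runtime container (RDS) embedding atoms, parameters and protocol.
#' @param dictionary,path Object and file path.
#' @return \code{read_dictionary} returns the \code{mrf_dictionary}.
#' @export
write_dictionary <- function(dictionary, path) {
  stop_if(!inherits(dictionary, "mrf_dictionary"), "not an mrf_dictionary")
  saveRDS(dictionary, path)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  x <- readRDS(path)
  stop_if(!inherits(x, "mrf_dictionary"), "file does not contain an mrf_dictionary")
  x
}
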