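#' Percolation fitness landscapes
#'
#' In a percolation (or "holey") landscape each of the `2^L` genotypes is
#' independently viable with probability `p` (fitness 1) and otherwise unfit
#' (fitness `w0`, 0 by default, i.e. lethal).  The viable genotypes form
#' percolation clusters on the hypercube; for forward simulation the landscape
#' is conditioned on the viable set being non-empty and connected under
#' single-point-mutation (Hamming distance 1) edges, so that the population
#' cannot start in an isolated cluster.
#'
#' `generate_connected_landscape()` draws landscapes by rejection: realizations
#' whose viable network is disconnected (or empty) are discarded.  Near the
#' percolation threshold acceptance becomes rare, hence the `max_attempts`
#' guard.
#'
#' @param L Number of loci (`>= 1`).
#' @param p Probability that a genotype is viable, in `(0, 1]` (a value of 0
#'   can never yield a viable genotype and fails after `max_attempts`).
#' @param w0 Fitness of unfit genotypes, in `[0, 1)`.  Default 0 (lethal).
#' @param max_attempts Maximum number of rejection-sampling attempts.
#' @param seed Optional integer seed for a private RNG stream; when `NULL`
#'   the current global RNG is consumed.
#' @return An object of class `percolation_landscape`: a list with elements
#'   `L`, `p`, `w0`, `viability` (logical vector of length `2^L` in genotype
#'   index order), `seed`, and `attempts` (number of rejection attempts used).
#' @examples
#' ls <- generate_connected_landscape(4, 0.7, seed = 1)
#' sum(ls$viability)
#' @export
generate_connected_landscape <- function(L, p, w0 = 0, max_attempts = 1e6,
                                         seed = NULL) {
  L <- as.integer(L)
  stopifnot(L >= 1L, p >= 0, p <= 1, w0 >= 0, w0 < 1, max_attempts >= 1)
  n <- bitwShiftL(1L, L)
  draw <- function() {
    for (attempt in seq_len(max_attempts)) {
      viab <- stats::runif(n) < p
      if (any(viab) && viable_network_connected(viab, L)) {
        return(list(viab = viab, attempts = attempt))
      }
    }
    stop(sprintf(paste0("no connected landscape in %d attempts ",
                        "(empirical acceptance fraction 0/%d); ",
                        "p = %g may be below the percolation threshold"),
                 max_attempts, max_attempts, p), call. = FALSE)
  }
  res <- if (is.null(seed)) draw() else with_private_rng(seed, draw())
  structure(list(L = L, p = p, w0 = w0, viability = res$viab,
                 seed = seed, attempts = res$attempts),
            class = "percolation_landscape")
}

#' @export
print.percolation_landscape <- function(x, ...) {
  cat(sprintf(
    "<percolation_landscape L=%d p=%g w0=%g  %d/%d viable (%d attempts)>\n",
    x$L, x$p, x$w0, sum(x$viability), length(x$viability), x$attempts))
  invisible(x)
}

# Evaluate an expression under a temporary, privately seeded RNG stream,
# leaving the global stream untouched.
with_private_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_seed) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Breadth-first search over the viable vertices of the hypercube using
# Hamming-1 edges.  "Connected" additionally requires >= 1 viable vertex.
viable_network_connected <- function(viability, L) {
  viable_idx <- which(viability) - 1L
  if (length(viable_idx) == 0L) return(FALSE)
  visited <- logical(length(viability))
  frontier <- viable_idx[1L]
  visited[frontier + 1L] <- TRUE
  nfound <- 1L
  while (length(frontier) > 0L) {
    nb <- unique(as.vector(neighbor_indices(frontier, L)))
    nb <- nb[viability[nb + 1L] & !visited[nb + 1L]]
    visited[nb + 1L] <- TRUE
    nfound <- nfound + length(nb)
    frontier <- nb
  }
  nfound == length(viable_idx)
}

#' Fitness of a genotype on a percolation landscape
#'
#' @param landscape A `percolation_landscape`.
#' @param g A [finite_genotype()] (its `L` must match the landscape).
#' @return `1` for viable genotypes, `landscape$w0` otherwise.
#' @export
landscape_fitness <- function(landscape, g) {
  check_genotype_landscape(g, landscape)
  if (landscape$viability[unclass(g)[1L] + 1L]) 1 else landscape$w0
}

check_genotype_landscape <- function(g, landscape) {
  if (!inherits(g, "finite_genotype") || attr(g, "L") != landscape$L) {
    stop("genotype and landscape have incompatible locus counts")
  }
  invisible(TRUE)
}

#' Mutational robustness of a genotype
#'
#' The fraction of a viable genotype's `L` single-mutant neighbors that are
#' viable; 0 for an unfit genotype.
#'
#' @inheritParams landscape_fitness
#' @return Numeric in `[0, 1]`.
#' @export
genotype_robustness <- function(landscape, g) {
  check_genotype_landscape(g, landscape)
  idx <- unclass(g)[1L]
  if (!landscape$viability[idx + 1L]) return(0)
  nb <- neighbor_indices(idx, landscape$L)
  mean(landscape$viability[nb + 1L])
}

# vectorized robustness over plain integer indices (hot path)
robustness_indices <- function(landscape, idx) {
  nb <- neighbor_indices(idx, landscape$L)           # length(idx) x L
  vi <- matrix(landscape$viability[nb + 1L], nrow = length(idx))
  out <- rowMeans(vi)
  out[!landscape$viability[idx + 1L]] <- 0
  out
}

#' Write a percolation landscape to a plain-text file
#'
#' The format has four header lines `L=<int>`, `p=<float>`, `w0=<float>`,
#' `seed=<int|NA>` followed by a single line of `0`/`1` characters of length
#' `2^L` giving the viability table in genotype index order.
#'
#' @param landscape A `percolation_landscape`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  lines <- c(
    sprintf("L=%d", landscape$L),
    sprintf("p=%.17g", landscape$p),
    sprintf("w0=%.17g", landscape$w0),
    sprintf("seed=%s", if (is.null(landscape$seed)) "NA"
            else as.character(landscape$seed)),
    paste(as.integer(landscape$viability), collapse = ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a percolation landscape written by [write_landscape()]
#'
#' Validates the table length and that the viable network is non-empty and
#' connected.
#'
#' @param path File path.
#' @return A `percolation_landscape`.
#' @export
read_landscape <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 5L) stop("truncated landscape file")
  hdr <- function(i, key) {
    kv <- strsplit(lines[i], "=", fixed = TRUE)[[1L]]
    if (kv[1L] != key) stop(sprintf("expected header '%s=' on line %d", key, i))
    kv[2L]
  }
  L <- as.integer(hdr(1L, "L"))
  p <- as.numeric(hdr(2L, "p"))
  w0 <- as.numeric(hdr(3L, "w0"))
  seed <- suppressWarnings(as.integer(hdr(4L, "seed")))
  viab <- as.integer(strsplit(lines[5L], "")[[1L]]) == 1L
  if (length(viab) != bitwShiftL(1L, L)) {
    stop("viability table length does not match 2^L")
  }
  if (!any(viab)) stop("landscape has no viable genotype")
  if (!viable_network_connected(viab, L)) {
    stop("viable network in landscape file is not connected")
  }
  structure(list(L = L, p = p, w0 = w0, viability = viab,
                 seed = if (is.na(seed)) NULL else seed, attempts = NA_integer_),
            class = "percolation_landscape")
}
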