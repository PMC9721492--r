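#' Simulation configuration
#'
#' Bundles all parameters of a Wright-Fisher run.  Exactly one genotype
#' representation must be selected: finite sites (`L` loci with per-site
#' mutation probability `mu`) or infinite sites (genome-wide rate `U`).
#'
#' @param N Population size (constant, `>= 1`).
#' @param L Number of loci (finite sites only).
#' @param mu Per-site mutation probability (finite sites only).
#' @param U Genome-wide mutation rate (infinite sites only).
#' @param r Recombination rate: the probability that an offspring has two
#'   parents (facultative sex), in `[0, 1]` -- except under
#'   `crossover = "obligate_poisson"`, where every offspring recombines and
#'   `r >= 0` is the mean number of crossover points.
#' @param p Fraction of viable genotypes in `[0, 1]`.
#' @param w0 Fitness of unfit genotypes in `[0, 1)`; 0 means lethal.
#' @param scheme Selection-recombination scheme: `"concurrent"` (selection and
#'   recombination in one fitness-proportional step), `"successive_simple"`
#'   (selection first, then fitness-blind recombination -- adds
#'   recombination-dependent genetic drift), or `"successive_pairs"`
#'   (selection first, then recombining survivors are pooled into mating
#'   pairs that produce complementary offspring -- drift stays independent of
#'   `r`).
#' @param crossover `"uniform"`, `"one_point"`, or `"obligate_poisson"`.
#' @param seed Optional integer seed recorded with the run.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(N, L = NULL, mu = NULL, U = NULL, r = 0, p = 1,
                       w0 = 0,
                       scheme = c("concurrent", "successive_simple",
                                  "successive_pairs"),
                       crossover = c("uniform", "one_point",
                                     "obligate_poisson"),
                       seed = NULL) {
  scheme <- match.arg(scheme)
  crossover <- match.arg(crossover)
  N <- as.integer(N)
  stopifnot(N >= 1L)
  finite_given <- !is.null(L) || !is.null(mu)
  infinite_given <- !is.null(U)
  if (finite_given && infinite_given) {
    stop("contradictory settings: both (mu, L) and U given; ",
         "choose finite sites (mu, L) or infinite sites (U)")
  }
  if (!finite_given && !infinite_given) {
    stop("either (mu, L) for finite sites or U for infinite sites required")
  }
  if (finite_given && (is.null(L) || is.null(mu))) {
    stop("finite sites requires both fields 'L' and 'mu'")
  }
  if (finite_given) {
    L <- as.integer(L)
    stopifnot(L >= 1L, mu >= 0, mu <= 1)
    if (crossover == "one_point" && L < 2L) {
      stop("field 'crossover': one_point requires L >= 2")
    }
  } else {
    stopifnot(U >= 0)
  }
  stopifnot(r >= 0, p >= 0, p <= 1, w0 >= 0, w0 < 1)
  if (crossover != "obligate_poisson" && r > 1) {
    stop("field 'r': recombination probability > 1 is only meaningful with ",
         "crossover = 'obligate_poisson' (mean number of crossovers)")
  }
  structure(list(N = N,
                 representation = if (finite_given) "finite" else "infinite",
                 L = L, mu = mu, U = U, r = r, p = p, w0 = w0,
                 scheme = scheme, crossover = crossover, seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  mut <- if (x$representation == "finite") {
    sprintf("L=%d mu=%g", x$L, x$mu)
  } else sprintf("U=%g", x$U)
  cat(sprintf("<sim_config N=%d %s r=%g p=%g w0=%g %s/%s seed=%s>\n",
              x$N, mut, x$r, x$p, x$w0, x$scheme, x$crossover,
              if (is.null(x$seed)) "NULL" else x$seed))
  invisible(x)
}

#' Initialize a monomorphic population
#'
#' Finite sites: all `N` individuals carry `start` (a [finite_genotype()] or a
#' raw index), by default a uniformly random viable genotype of the landscape.
#' Infinite sites: all individuals carry the empty mutation set (the ancestral
#' genotype, viable by construction).
#'
#' @param cfg A [sim_config()].
#' @param world A `percolation_landscape` (finite sites) or [ism_oracle()]
#'   (infinite sites).
#' @param start Optional start genotype (finite sites).
#' @return An object of class `wf_population`.
#' @export
new_population <- function(cfg, world, start = NULL) {
  N <- cfg$N
  if (cfg$representation == "finite") {
    stopifnot(inherits(world, "percolation_landscape"),
              world$L == cfg$L)
    if (is.null(start)) {
      viable_idx <- which(world$viability) - 1L
      start <- viable_idx[sample.int(length(viable_idx), 1L)]
    } else if (inherits(start, "finite_genotype")) {
      start <- unclass(start)[1L]
    }
    geno <- rep(as.integer(start), N)
    fitness <- ifelse(world$viability[geno + 1L], 1, world$w0)
    pop <- list(representation = "finite", N = N, L = cfg$L, geno = geno,
                fitness = fitness, generation = 0L, tally = NULL)
  } else {
    stopifnot(inherits(world, "ism_oracle"))
    # `keys` caches each individual's canonical mutation-set key; it is
    # maintained by wf_step()/detect_and_purge_fixations().  Code that edits
    # `sets` directly must set `keys` to NULL (it is then recomputed).
    pop <- list(representation = "infinite", N = N,
                sets = rep(list(integer(0)), N), keys = rep("0", N),
                pos = numeric(0), next_id = 1L,
                fitness = rep(1, N), generation = 0L, tally = NULL)
  }
  structure(pop, class = "wf_population")
}

#' @export
print.wf_population <- function(x, ...) {
  if (x$representation == "finite") {
    cat(sprintf(
      "<wf_population finite N=%d L=%d gen=%d  %d distinct genotypes>\n",
      x$N, x$L, x$generation, length(unique(x$geno))))
  } else {
    cat(sprintf(
      "<wf_population infinite N=%d gen=%d  %d segregating mutations>\n",
      x$N, x$generation, length(unique(unlist(x$sets)))))
  }
  invisible(x)
}

# canonical keys of all individuals (infinite sites), using the cache
# maintained by wf_step() when available
get_keys <- function(pop) {
  if (!is.null(pop$keys)) pop$keys
  else vapply(pop$sets, ism_key, character(1))
}
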