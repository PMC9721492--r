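#' Lazy fitness oracle for the infinite-sites model
#'
#' In the infinite-sites model the sequence space is unbounded, so viability
#' cannot be tabulated up front.  Instead, the fitness of a genotype --
#' identified by its canonical mutation set relative to the current fixed
#' background -- is drawn (viable with probability `p`) the first time the
#' genotype is encountered, and cached so that it never changes afterwards.
#' The ancestral genotype (empty mutation set) is viable by construction.
#'
#' The oracle keeps its own RNG stream so that a landscape realization is
#' reproducible independently of how much randomness the population dynamics
#' consume.
#'
#' When a mutation fixes (reaches all `N` individuals) it joins the background:
#' cached genotypes whose mutation set lacks the fixed mutation can never be
#' revisited (there are no back mutations) and are purged, and the remaining
#' keys are rewritten with the fixed identifier removed.
#'
#' @param p Viability probability in `[0, 1]`.
#' @param seed Integer seed for the oracle's private RNG stream; when `NULL`
#'   a seed is drawn from the global RNG.
#' @return An object of class `ism_oracle` (an environment with reference
#'   semantics) with fields `p`, `cache`, `fixed` (identifiers fixed so far),
#'   and `rng_state`.
#' @export
ism_oracle <- function(p, seed = NULL) {
  stopifnot(p >= 0, p <= 1)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  o <- new.env(parent = emptyenv())
  o$p <- p
  o$cache <- new.env(hash = TRUE, parent = emptyenv())
  o$fixed <- integer(0)
  o$seed <- seed
  o$rng_state <- with_private_rng(seed, get(".Random.seed", globalenv()))
  o$cache[["0"]] <- TRUE   # ancestral genotype is viable
  class(o) <- "ism_oracle"
  o
}

#' @export
print.ism_oracle <- function(x, ...) {
  cat(sprintf("<ism_oracle p=%g  %d cached genotypes, %d fixed mutations>\n",
              x$p, length(ls(x$cache)), length(x$fixed)))
  invisible(x)
}

# canonical cache key of an id set: sorted ids, "0" for the empty set
ism_key <- function(ids) {
  if (length(ids) == 0L) "0" else paste(sort.int(ids), collapse = ",")
}

# vectorized: which keys contain `fixed_id`, and those keys rewritten with
# the identifier deleted (it becomes background); "0" denotes the empty set
rebase_keys <- function(keys, fixed_id) {
  if (length(keys) == 0L) {
    return(list(keep = logical(0), new = character(0)))
  }
  delim <- paste0(",", keys, ",")
  token <- paste0(",", fixed_id, ",")
  keep <- grepl(token, delim, fixed = TRUE)
  new <- sub(token, ",", delim[keep], fixed = TRUE)
  new <- substr(new, 2L, nchar(new) - 1L)
  new[new == ""] <- "0"
  list(keep = keep, new = new)
}

# draw n uniforms from the oracle's private stream
oracle_draw <- function(oracle, n) {
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", oracle$rng_state, globalenv())
  u <- stats::runif(n)
  oracle$rng_state <- get(".Random.seed", globalenv(), inherits = FALSE)
  if (has_seed) assign(".Random.seed", old, globalenv())
  else rm(".Random.seed", envir = globalenv())
  u
}

# vectorized viability lookup over precomputed canonical keys; uncached keys
# are drawn in order of first appearance (deterministic given the oracle seed)
oracle_viability_keys <- function(oracle, keys) {
  cache <- oracle$cache
  out <- logical(length(keys))
  known <- logical(length(keys))
  for (i in seq_along(keys)) {
    v <- cache[[keys[i]]]
    if (!is.null(v)) {
      out[i] <- v
      known[i] <- TRUE
    }
  }
  if (!all(known)) {
    new_keys <- unique(keys[!known])
    u <- oracle_draw(oracle, length(new_keys))
    viable <- u < oracle$p
    for (i in seq_along(new_keys)) cache[[new_keys[i]]] <- viable[i]
    out[!known] <- viable[match(keys[!known], new_keys)]
  }
  out
}

#' Query (and lazily draw) the viability of an infinite-sites genotype
#'
#' @param oracle An [ism_oracle()].
#' @param ids Integer vector of mutation identifiers relative to the current
#'   fixed background (a [mutation_set()] is also accepted).  Must not contain
#'   already-fixed identifiers.
#' @return Logical: is the genotype viable?  Repeated calls with the same set
#'   always return the first draw.
#' @export
ism_fitness <- function(oracle, ids) {
  if (inherits(ids, "mutation_set")) ids <- ids$ids
  ids <- as.integer(ids)
  if (length(oracle$fixed) && any(ids %in% oracle$fixed)) {
    stop("mutation set contains an already-fixed identifier; ",
         "keys must be expressed relative to the fixed background")
  }
  oracle_viability_keys(oracle, ism_key(ids))
}

#' Purge the oracle cache after a mutation fixes
#'
#' Removes every cached genotype whose mutation set lacks `fixed_id` (such
#' genotypes are unreachable once the mutation is in the background) and
#' rewrites the remaining keys with `fixed_id` deleted.
#'
#' @param oracle An [ism_oracle()].
#' @param fixed_id The newly fixed mutation identifier.
#' @return The number of purged cache entries, invisibly.
#' @export
purge_on_fixation <- function(oracle, fixed_id) {
  fixed_id <- as.integer(fixed_id)
  cache <- oracle$cache
  keys <- ls(cache, sorted = FALSE)
  reb <- rebase_keys(keys, fixed_id)
  # drop unreachable keys first: a rebased key may coincide with a key that
  # lacks the fixed mutation and must not be clobbered by the rebase
  rm(list = keys[!reb$keep], envir = cache)
  if (any(reb$keep)) {
    vals <- mget(keys[reb$keep], envir = cache)
    rm(list = keys[reb$keep], envir = cache)
    for (i in seq_along(vals)) cache[[reb$new[i]]] <- vals[[i]]
  }
  oracle$fixed <- c(oracle$fixed, fixed_id)
  invisible(sum(!reb$keep))
}
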