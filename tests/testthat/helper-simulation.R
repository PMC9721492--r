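# shared helpers: hand-built landscapes and small run loops

# wrap an explicit viability table (logical, length 2^L) as a landscape
manual_landscape <- function(viability, p = 0.5, w0 = 0) {
  L <- as.integer(round(log2(length(viability))))
  stopifnot(bitwShiftL(1L, L) == length(viability))
  structure(list(L = L, p = p, w0 = w0, viability = viability,
                 seed = NULL, attempts = 1L),
            class = "percolation_landscape")
}

step_n <- function(pop, cfg, world, n) {
  for (i in seq_len(n)) pop <- wf_step(pop, cfg, world)
  pop
}

# one-generation allele-count experiment at a single fully viable locus:
# start at allele frequency 1/2, return the derived allele count after one
# generation under the given scheme and recombination rate
allele_count_one_gen <- function(scheme, r, N = 100L, nreps = 1000L) {
  cfg <- sim_config(N = N, L = 1, mu = 0, r = r, p = 1, scheme = scheme)
  world <- manual_landscape(c(TRUE, TRUE), p = 1)
  start <- rep(c(0L, 1L), N / 2L)
  proto <- new_population(cfg, world, start = 0L)
  proto$geno <- start
  vapply(seq_len(nreps), function(i) sum(wf_step(proto, cfg, world)$geno),
         integer(1))
}
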