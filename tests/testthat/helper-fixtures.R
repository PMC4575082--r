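# Small in-code fixtures used across test files.

# Table from a compact spec: list of individuals, each a named list of
# allele vectors; ploidy defaults to 2.
make_table <- function(spec, ploidy = NULL, markers = NULL, ...) {
  GenotypeTable(spec, ploidy = ploidy, markers = markers, ...)
}

# Random table with optional triploids and missing cells, for round-trip and
# property tests.
random_table <- function(seed, n = 6, m = 4, triploid = TRUE, missing = TRUE) {
  set.seed(seed)
  pl <- if (triploid) sample(c(2L, 3L), n, replace = TRUE) else rep(2L, n)
  calls <- matrix(vector("list", n * m), n, m)
  for (i in seq_len(n)) for (l in seq_len(m)) {
    if (missing && runif(1) < 0.15) {
      calls[[i, l]] <- integer(0)
    } else {
      k <- sample.int(pl[i], 1)   # observed copies (dosage-ambiguity allowed)
      calls[[i, l]] <- sort(sample(seq(100L, 120L, by = 2L), k, replace = TRUE))
    }
  }
  lg <- paste0("LG", rep_len(1:3, m))
  GenotypeTable(calls, ids = sprintf("g%02d", seq_len(n)), ploidy = pl,
                markers = data.frame(name = sprintf("loc%02d", seq_len(m)),
                                     linkage_group = lg,
                                     stringsAsFactors = FALSE))
}

# Two populations fixed for different alleles at every locus.
fixed_two_pop_table <- function(nPerPop = 4, m = 3) {
  n <- 2 * nPerPop
  calls <- matrix(vector("list", n * m), n, m)
  for (i in seq_len(n)) for (l in seq_len(m)) {
    allele <- if (i <= nPerPop) 100L else 120L
    calls[[i, l]] <- c(allele, allele)
  }
  GenotypeTable(calls, ids = sprintf("i%02d", seq_len(n)))
}

rdirichlet_h <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), n, length(alpha),
              byrow = TRUE)
  x / rowSums(x)
}

panel <- pearPanelStats()
panel_dp <- setNames(panel$DP, panel$locus)
panel_lg <- setNames(panel$linkage_group, panel$locus)
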