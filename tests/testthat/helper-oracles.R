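# Shared independent oracles and small builders used across test files.

# physical constants, restated independently of the package's bundle
RT_KJ <- 8.314 * 298.15 / 1000       # kJ/mol at 298.15 K
FARADAY <- 96485                     # C/mol
HARTREE_KJ <- 2625.50

# brute-force Boltzmann average (plain summation, no stabilization)
brute_boltzmann <- function(e_hartree, t_k = 298.15) {
  rt <- 8.314 * t_k / 1000
  w <- exp(-(e_hartree - min(e_hartree)) * HARTREE_KJ / rt)
  sum(e_hartree * w) / sum(w)
}

# brute-force pseudoisomer aggregate by direct summation
brute_pseudoisomer <- function(g_kj, t_k = 298.15) {
  rt <- 8.314 * t_k / 1000
  -rt * log(sum(exp(-g_kj / rt)))
}

# exhaustive O(n^2) pair matcher over explicit group vectors
brute_match_pairs <- function(compounds, delta, max_carbons = 7) {
  gv <- lapply(compounds$group_vector, function(s) {
    v <- jsonlite::fromJSON(s)
    stats::setNames(as.integer(unlist(v)), names(v))
  })
  basis <- sort(unique(c(unlist(lapply(gv, names)), names(delta))))
  full <- function(v) {
    out <- stats::setNames(rep(0L, length(basis)), basis)
    out[names(v)] <- v
    out
  }
  gv <- lapply(gv, full)
  target <- full(delta)
  hits <- character()
  for (i in seq_len(nrow(compounds))) {
    for (j in seq_len(nrow(compounds))) {
      if (i == j) next
      if (compounds$n_carbons[i] >= max_carbons ||
          compounds$n_carbons[j] >= max_carbons) next
      if (all(gv[[j]] - gv[[i]] == target)) {
        hits <- c(hits, paste(compounds$id[i], compounds$id[j], sep = "__"))
      }
    }
  }
  sort(hits)
}

# two-carbon slice of the toy set in which each signature has exactly one match
toy_core_compounds <- function() {
  comp <- simulate_compound_set()
  comp[comp$id %in% c("C01", "C02", "C03", "C04", "C05", "C14"), ]
}

# toy pair table for fingerprint/pipeline tests
toy_pairs <- function(compounds = simulate_compound_set()) {
  p <- enumerate_redox_pairs(compounds)
  sugar_name_filter(chirality_filter(p, compounds), compounds)
}
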