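# Shared fixtures, built in code. One small world is generated once per test
# run and reused read-only across files.

options(ferrotarget.log_level = "quiet")

small_world_config <- function(seed = 3, ...) {
  world_config(n_genes = 300L, n_cell_lines = 12L, n_kd_genes = 80L,
               n_profiles = 10L, seed = seed, ...)
}

.small_world_cache <- new.env(parent = emptyenv())

small_world <- function(seed = 3) {
  key <- paste0("w", seed)
  if (is.null(.small_world_cache[[key]]))
    .small_world_cache[[key]] <- generate_world(small_world_config(seed))
  .small_world_cache[[key]]
}

# quick list of fc profiles from a matrix of log2fc values (genes x profiles)
profiles_from_matrix <- function(m, p_values = NULL) {
  lapply(seq_len(ncol(m)), function(j)
    fc_profile(colnames(m)[j], rownames(m), m[, j],
               if (!is.null(p_values)) p_values[, j] else NULL))
}

random_gene_matrix <- function(n, p, seed = 1, prefix = "g") {
  with_seed <- function(s, expr) { set.seed(s); expr }
  with_seed(seed, {
    m <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("%s%03d", prefix, seq_len(n)),
                                sprintf("s%03d", seq_len(p))))
    m
  })
}
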