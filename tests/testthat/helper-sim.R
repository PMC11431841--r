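# Shared fixtures built in code.

# Small, fast simulation configuration for unit tests.
tiny_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_samples = 24, n_males = 4, n_trios = 4,
                   n_autosomal_sites = 800, n_x_nonpar_sites = 120,
                   n_y_sites = 5, n_par_sites = 15, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Hand-built 2-sample genotype matrix.
toy_geno <- function(calls, chrom = NULL, pos = NULL) {
  n <- ncol(calls)
  geno_matrix(calls,
              samples = paste0("s", seq_len(nrow(calls))),
              sites = data.frame(chrom = chrom %||% rep("1", n),
                                 pos = pos %||% seq_len(n) * 100L,
                                 ref = rep("A", n), alt = rep("G", n),
                                 snp_id = paste0("snp", seq_len(n))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force Mendelian oracle: enumerate each parent's gamete
# set explicitly and check whether the child's genotype is a reachable sum.
oracle_mendelian <- function(f, m, c) {
  gam <- function(g) switch(as.character(g), "0" = 0L, "1" = c(0L, 1L), "2" = 1L)
  c %in% outer(gam(f), gam(m), `+`)
}
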