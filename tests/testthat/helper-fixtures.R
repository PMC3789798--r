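# Small in-code fixtures shared across test files.

toy_annotation <- function() {
  genome_annotation(
    chromosomes = data.frame(name = c("chrA", "chrB"),
                             length = c(300000, 900000),
                             centromere = c(150000, 200000)),
    genes = data.frame(
      gene_id = c("gA1", "gA2", "gA3", "gA4", "gB1", "gB2"),
      chrom = c("chrA", "chrA", "chrA", "chrA", "chrB", "chrB"),
      start = c(900, 9500, 99500, 160500, 49500, 250500),
      end = c(1100, 10500, 100500, 161500, 50500, 251500),
      strand = c("+", "-", "+", "+", "-", "+")))
}

# uniform-rate, noise-free two-chromosome simulation
uniform_sim_config <- function(seed = 7, n_genes = 30, rho0_kb = 0,
                               residual_fraction = 1, ...) {
  sim_config(seed = seed,
             genome = data.frame(name = c("chrA", "chrB"),
                                 length = c(3e5, 9e5),
                                 centromere = c(15e4, 2e5)),
             n_genes = n_genes, noise_sd = 0, interaction_rate = 0,
             replicate_count = 1, rho0_kb = rho0_kb,
             residual_fraction = residual_fraction, ...)
}

no_self_norm <- function() distance_config(self_normalization = "none")

# pair distances joined to simulation truth
joined_truth <- function(sim, ch, config = no_self_norm()) {
  d <- estimate_distances(sim$screens[[ch]], config)
  d <- d[!d$is_self, , drop = FALSE]
  tr <- sim$truth[sim$truth$chrom == ch, ]
  m <- match(paste(d$query_id, d$array_id), paste(tr$query_id, tr$array_id))
  cbind(d, tr[m, c("R_true", "cm_true", "gd_true")])
}
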