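# Synthetic two-clade study fixture shared with the acceptance suite.
make_study <- function(dir, n_post = 4, n_slices = 10, seed = 1) {
  hab_dir <- file.path(dir, "maps")
  dir.create(hab_dir, recursive = TRUE, showWarnings = FALSE)
  k_t <- round(seq(3, 12, length.out = n_slices))
  sim <- simulate_habitat_stack(n_slices, k = k_t, seed = seed)
  paths <- file.path(hab_dir, sprintf("habitat_%dMa.asc", seq_len(n_slices) - 1))
  for (i in seq_len(n_slices)) write_ascii_grid(sim$stack$slices[[i]], paths[i])
  manifest <- file.path(dir, "maps.tsv")
  write.table(data.frame(path = paths, age_Ma = seq_len(n_slices) - 1),
              manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  env <- build_env_series(sim$stack, "patch_count")

  write_clade <- function(name, rate, f, crown, seed0) {
    trees <- lapply(seq_len(n_post + 1), function(i)
      simulate_tree(rate, f = f, crown_age = crown, seed = seed0 + i))
    consensus <- file.path(dir, paste0(name, "_consensus.nwk"))
    posterior <- file.path(dir, paste0(name, "_posterior.nwk"))
    writeLines(ape::write.tree(trees[[1]]$phy), consensus)
    writeLines(vapply(trees[-1], function(ch) ape::write.tree(ch$phy),
                      character(1)), posterior)
    list(name = name, consensus = consensus, posterior = posterior,
         sampling_fraction = f)
  }
  clades <- list(
    write_clade("cst_clade", constant_rates(0.25, 0.05), 0.9, 14, 100),
    write_clade("env_clade",
                env_rates("M2.2", c(alpha = 0.04, beta = 0.25, mu = 0.02),
                          env), 0.9, 14, 200))
  list(clades = clades, manifest = manifest, env = env)
}

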